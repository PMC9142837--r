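# File formats: JSON model/suite/solution documents, TSV interaction
# tables, CSV trajectory tables, DOT/GraphML network export.

.sign_label <- function(sign) ifelse(sign, "activate", "repress")

.sign_parse <- function(lab, where) {
  out <- match(lab, c("repress", "activate")) - 1L
  if (anyNA(out))
    stop("malformed sign token '", lab[is.na(out)][1L], "' in ", where,
         " (expected 'activate' or 'repress')")
  out == 1L
}

#' Read and write abstract Boolean network files
#'
#' Models are stored as versioned JSON documents with sections
#' `components` (name, role, menu), and `interactions` (source, target,
#' `sign` in `{"activate","repress"}`, `definite`). `write_model()` then
#' `read_model()` is the identity.
#'
#' @param x An [abn].
#' @param path File path.
#' @return `read_model()` returns an [abn]; `write_model()` returns `path`
#'   invisibly.
#' @export
write_model <- function(x, path) {
  stopifnot(inherits(x, "abn"))
  doc <- list(
    format_version = 1L,
    components = lapply(seq_len(nrow(x$components)), function(i)
      list(name = x$components$name[i], role = x$components$role[i],
           menu = x$menus[[x$components$name[i]]])),
    interactions = lapply(seq_len(nrow(x$interactions)), function(i)
      list(source = x$interactions$source[i],
           target = x$interactions$target[i],
           sign = .sign_label(x$interactions$sign[i]),
           definite = x$interactions$definite[i])))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$format_version))
    stop("not a model document (missing format_version): ", path)
  comps <- data.frame(
    name = vapply(doc$components, function(c) c$name, ""),
    role = vapply(doc$components, function(c) c$role %||% "gene", ""),
    stringsAsFactors = FALSE)
  menus <- lapply(doc$components, function(c) unlist(c$menu))
  names(menus) <- comps$name
  ia <- if (length(doc$interactions)) {
    data.frame(
      source = vapply(doc$interactions, function(e) e$source, ""),
      target = vapply(doc$interactions, function(e) e$target, ""),
      sign = .sign_parse(vapply(doc$interactions, function(e) e$sign, ""),
                         path),
      definite = vapply(doc$interactions, function(e) isTRUE(e$definite), TRUE),
      stringsAsFactors = FALSE)
  } else NULL
  abn(comps, interactions = ia, menus = menus)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write experiment-suite files
#'
#' Suites are JSON documents: each experiment carries `label`, `length`,
#' `perturbations` (component, mode) and `constraints` (time, component,
#' value, role). Round-trips exactly.
#'
#' @param x An [experiment_suite].
#' @param path File path.
#' @return `read_suite()` returns an [experiment_suite].
#' @export
write_suite <- function(x, path) {
  if (inherits(x, "abn_experiment")) x <- experiment_suite(x)
  stopifnot(inherits(x, "experiment_suite"))
  doc <- list(
    format_version = 1L,
    experiments = lapply(unclass(x), function(e)
      list(label = e$label, length = e$length,
           perturbations = lapply(seq_len(nrow(e$perturbations)), function(i)
             list(component = e$perturbations$component[i],
                  mode = e$perturbations$mode[i])),
           constraints = lapply(seq_len(nrow(e$constraints)), function(i)
             list(time = e$constraints$time[i],
                  component = e$constraints$component[i],
                  value = e$constraints$value[i],
                  role = e$constraints$role[i])))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_suite
#' @export
read_suite <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$format_version))
    stop("not a suite document (missing format_version): ", path)
  exps <- lapply(doc$experiments, function(e) {
    pert <- if (length(e$perturbations)) {
      data.frame(component = vapply(e$perturbations, function(p) p$component, ""),
                 mode = vapply(e$perturbations, function(p) p$mode, ""),
                 stringsAsFactors = FALSE)
    } else NULL
    cons <- if (length(e$constraints)) {
      data.frame(time = vapply(e$constraints, function(c) as.integer(c$time), 1L),
                 component = vapply(e$constraints, function(c) c$component, ""),
                 value = vapply(e$constraints, function(c) isTRUE(c$value), TRUE),
                 role = vapply(e$constraints, function(c) c$role, ""),
                 stringsAsFactors = FALSE)
    } else NULL
    experiment(e$label, length = e$length, perturbations = pert,
               constraints = cons)
  })
  experiment_suite(exps)
}

#' Read and write concrete-network (solution) files
#'
#' A solution document embeds the full model plus the chosen optional
#' interactions and the condition assignment.
#'
#' @param x A [concrete_network].
#' @param path File path.
#' @export
write_solution <- function(x, path) {
  stopifnot(inherits(x, "concrete_network"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_model(x$abn, tmp)
  doc <- jsonlite::read_json(tmp)
  doc$solution <- list(chosen_optional = as.logical(x$chosen_optional),
                       conditions = as.list(x$conditions))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_solution
#' @export
read_solution <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$solution)) stop("not a solution document: ", path)
  net <- read_model(path)
  concrete_network(net,
                   chosen_optional = unlist(doc$solution$chosen_optional) %||% logical(),
                   conditions = unlist(doc$solution$conditions))
}

#' Import an interaction table (TSV mirror of the data-collection table)
#'
#' Reads a tab-separated table with columns `Source`, `Regulates`
#' (`act`/`rep`), `Target` and `Definite` (`definite`/`optional` or
#' `TRUE`/`FALSE`) into the interaction data-frame format used by [abn()].
#'
#' @param path TSV file path.
#' @return Data frame with columns `source`, `target`, `sign`, `definite`.
#' @export
read_interaction_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("Source", "Regulates", "Target", "Definite")
  if (!all(need %in% names(tb)))
    stop("interaction table must have columns ", paste(need, collapse = ", "))
  reg <- tolower(tb$Regulates)
  bad <- !reg %in% c("act", "rep")
  if (any(bad))
    stop("malformed sign token '", tb$Regulates[bad][1L], "' in row ",
         which(bad)[1L], " of ", path)
  def <- tolower(as.character(tb$Definite))
  bad <- !def %in% c("definite", "optional", "true", "false")
  if (any(bad))
    stop("malformed Definite token '", tb$Definite[bad][1L], "' in row ",
         which(bad)[1L], " of ", path)
  data.frame(source = tb$Source, target = tb$Target, sign = reg == "act",
             definite = def %in% c("definite", "true"),
             stringsAsFactors = FALSE)
}

#' Trajectory tables
#'
#' Renders a trajectory as a 0/1 table, one row per time step, columns
#' ordered by first-activation time (components never active last, ties by
#' name), as gene-activity simulation figures order them.
#'
#' @param traj An `abn_trajectory`.
#' @param ordering `"activation"` (default) or `"name"`.
#' @return Data frame with a `step` column followed by one 0/1 column per
#'   component.
#' @export
render_trajectory_table <- function(traj, ordering = c("activation", "name")) {
  ordering <- match.arg(ordering)
  stopifnot(inherits(traj, "abn_trajectory"))
  first_on <- apply(traj, 2L, function(col) {
    w <- which(col)
    if (length(w)) w[1L] else nrow(traj) + 1L
  })
  ord <- if (ordering == "activation")
    order(first_on, colnames(traj)) else order(colnames(traj))
  out <- data.frame(step = as.integer(rownames(traj)),
                    matrix(as.integer(traj[, ord, drop = FALSE]),
                           nrow = nrow(traj)))
  names(out) <- c("step", colnames(traj)[ord])
  out
}

#' @rdname render_trajectory_table
#' @param path CSV file path.
#' @export
write_trajectory_csv <- function(traj, path, ordering = "activation") {
  utils::write.csv(render_trajectory_table(traj, ordering), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname render_trajectory_table
#' @export
read_trajectory_csv <- function(path) {
  tb <- utils::read.csv(path, check.names = FALSE)
  stopifnot(names(tb)[1L] == "step")
  m <- as.matrix(tb[, -1L, drop = FALSE]) == 1
  dimnames(m) <- list(tb$step, names(tb)[-1L])
  structure(m, class = "abn_trajectory")
}

#' Export a network drawing
#'
#' Writes the interaction graph in DOT or GraphML format. Activation edges
#' carry a normal arrowhead and repression edges a T-bar (`arrowhead=tee`);
#' optional interactions are dashed, definite ones solid.
#'
#' @param x An [abn] or [concrete_network] (for a concrete network only the
#'   effective interactions are drawn).
#' @param path Output file path.
#' @param format `"dot"` or `"graphml"`.
#' @export
export_network <- function(x, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  if (inherits(x, "concrete_network")) {
    ia <- effective_interactions(x)
    comps <- x$abn$components
  } else {
    stopifnot(inherits(x, "abn"))
    ia <- x$interactions
    comps <- x$components
  }
  if (format == "dot") {
    lines <- c("digraph network {", "  node [shape=box];")
    lines <- c(lines, sprintf('  "%s";', comps$name))
    if (nrow(ia)) {
      lines <- c(lines, sprintf(
        '  "%s" -> "%s" [arrowhead=%s, style=%s];',
        ia$source, ia$target,
        ifelse(ia$sign, "normal", "tee"),
        ifelse(ia$definite, "solid", "dashed")))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      if (nrow(ia)) ia[, c("source", "target", "sign", "definite")] else
        data.frame(source = character(), target = character()),
      directed = TRUE, vertices = comps)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Plot an abstract Boolean network
#'
#' Draws the interaction graph with activation in black, repression in red,
#' optional interactions dashed.
#'
#' @param x An [abn].
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.abn <- function(x, ...) {
  g <- igraph::graph_from_data_frame(
    x$interactions[, c("source", "target", "sign", "definite")],
    directed = TRUE, vertices = x$components)
  igraph::plot.igraph(
    g,
    edge.color = ifelse(igraph::E(g)$sign, "black", "firebrick"),
    edge.lty = ifelse(igraph::E(g)$definite, 1, 2),
    vertex.shape = "rectangle", vertex.size = 28, vertex.size2 = 12,
    vertex.color = "white", vertex.label.cex = 0.7, ...)
  invisible(x)
}
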