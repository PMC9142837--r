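# Abstract Boolean Networks: components, signed definite/optional
# interactions, and per-component menus of admissible regulation conditions.

#' Construct an abstract Boolean network
#'
#' An abstract Boolean network (ABN) couples a component set with definite
#' interactions (present in every concretization), optional interactions
#' (individually included or excluded by the synthesizer) and, for each
#' component, a non-empty menu of admissible regulation-condition indices.
#' Its concretizations -- one subset of the optional edges plus one condition
#' per component -- form a family of Boolean networks of size
#' `2^n_optional * prod(menu sizes)`.
#'
#' @param components Character vector of component names, or a data frame
#'   with columns `name` and `role` (one of `"gene"`, `"signal"`,
#'   `"fate-readout"`).
#' @param interactions Data frame with columns `source`, `target`,
#'   `sign` (logical, `TRUE` = activation) and `definite` (logical).
#' @param menus Named list mapping each component name to an integer vector
#'   of condition indices in `0..17`. Components left unnamed default to
#'   `default_menu`.
#' @param default_menu Integer vector used for components absent from `menus`.
#' @return An object of class `abn`.
#' @examples
#' net <- abn(c("A", "B"),
#'            interactions = data.frame(source = "A", target = "B",
#'                                      sign = TRUE, definite = TRUE),
#'            menus = list(B = 5L))
#' net
#' @export
abn <- function(components, interactions = NULL, menus = list(),
                default_menu = 0:17) {
  if (is.character(components)) {
    components <- data.frame(name = components,
                             role = rep("gene", length(components)),
                             stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(components), all(c("name", "role") %in% names(components)))
  components$name <- as.character(components$name)
  components$role <- as.character(components$role)
  if (anyDuplicated(components$name))
    stop("component names must be unique")
  bad_role <- setdiff(components$role, c("gene", "signal", "fate-readout"))
  if (length(bad_role))
    stop("unknown component role: ", paste(bad_role, collapse = ", "))

  if (is.null(interactions)) {
    interactions <- data.frame(source = character(), target = character(),
                               sign = logical(), definite = logical(),
                               stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(interactions),
            all(c("source", "target", "sign", "definite") %in% names(interactions)))
  interactions <- data.frame(source = as.character(interactions$source),
                             target = as.character(interactions$target),
                             sign = as.logical(interactions$sign),
                             definite = as.logical(interactions$definite),
                             stringsAsFactors = FALSE)
  unknown <- setdiff(unique(c(interactions$source, interactions$target)),
                     components$name)
  if (length(unknown))
    stop("interaction endpoint not declared as a component: ",
         paste(unknown, collapse = ", "))
  key <- paste(interactions$source, interactions$target, interactions$sign)
  if (anyDuplicated(key))
    stop("duplicate signed interaction (a triple may not be both definite and optional): ",
         key[duplicated(key)][1L])

  full_menus <- stats::setNames(rep(list(as.integer(default_menu)),
                                    nrow(components)), components$name)
  if (length(menus)) {
    bad <- setdiff(names(menus), components$name)
    if (length(bad)) stop("menu for undeclared component: ", paste(bad, collapse = ", "))
    for (nm in names(menus)) full_menus[[nm]] <- as.integer(menus[[nm]])
  }
  for (nm in names(full_menus)) {
    m <- full_menus[[nm]]
    if (length(m) == 0L || anyNA(m) || any(m < 0L | m > 17L) || anyDuplicated(m))
      stop("menu for ", nm, " must be a non-empty set of indices in 0..17")
    full_menus[[nm]] <- sort(m)
  }

  structure(list(components = components, interactions = interactions,
                 menus = full_menus),
            class = "abn")
}

#' @export
print.abn <- function(x, ...) {
  s <- network_summary(x)
  cat("Abstract Boolean network\n")
  cat("  components:       ", s$components, "\n")
  cat("  interactions:     ", s$interactions,
      " (", s$definite, " definite, ", s$optional, " optional)\n", sep = "")
  cat("  state space:      ", format(s$state_space, big.mark = ","), "\n", sep = "")
  cat("  concretizations:  ", format(s$model_space, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Structural counts for an abstract Boolean network
#'
#' @param x An [abn] object.
#' @return A list with `components`, `definite`, `optional`, `interactions`,
#'   `state_space` (`2^components`) and `model_space`
#'   (`2^optional * prod(menu sizes)`).
#' @export
network_summary <- function(x) {
  stopifnot(inherits(x, "abn"))
  n <- nrow(x$components)
  nd <- sum(x$interactions$definite)
  no <- sum(!x$interactions$definite)
  list(components = n, definite = nd, optional = no,
       interactions = nd + no,
       state_space = 2^n,
       model_space = 2^no * prod(vapply(x$menus, length, 1L)))
}

#' @export
summary.abn <- function(object, ...) {
  s <- network_summary(object)
  structure(s, class = "summary.abn")
}

#' @export
print.summary.abn <- function(x, ...) {
  cat("ABN summary: ", x$components, " components, ", x$interactions,
      " interactions (", x$definite, " definite + ", x$optional,
      " optional), state space ", format(x$state_space, big.mark = ","),
      ", model space ", format(x$model_space, big.mark = ","), "\n", sep = "")
  invisible(x)
}

# rows of the optional interactions, in declaration order
optional_interactions <- function(x) {
  x$interactions[!x$interactions$definite, , drop = FALSE]
}

#' Concretize an abstract Boolean network
#'
#' Selects a subset of the optional interactions and one regulation condition
#' per component, yielding an ordinary Boolean network.
#'
#' @param abn An [abn] object.
#' @param chosen_optional Logical vector over the ABN's optional interactions
#'   (in their declaration order), or an integer vector of indices into that
#'   order. `NULL` selects none.
#' @param conditions Named integer vector giving one condition index per
#'   component; every value must belong to that component's menu. Components
#'   omitted default to the first (lowest) entry of their menu.
#' @return An object of class `concrete_network`.
#' @export
concrete_network <- function(abn, chosen_optional = NULL, conditions = NULL) {
  stopifnot(inherits(abn, "abn"))
  opt <- optional_interactions(abn)
  m <- nrow(opt)
  if (is.null(chosen_optional)) {
    sel <- rep(FALSE, m)
  } else if (is.logical(chosen_optional)) {
    if (length(chosen_optional) != m)
      stop("chosen_optional must have one flag per optional interaction (", m, ")")
    sel <- chosen_optional
  } else {
    idx <- as.integer(chosen_optional)
    if (length(idx) && (min(idx) < 1L || max(idx) > m))
      stop("optional-interaction index out of range")
    sel <- seq_len(m) %in% idx
  }
  nm <- abn$components$name
  cond <- vapply(abn$menus, `[`, 1L, 1L)
  if (!is.null(conditions)) {
    if (is.null(names(conditions)) && length(conditions) == length(nm))
      names(conditions) <- nm
    bad <- setdiff(names(conditions), nm)
    if (length(bad)) stop("condition for undeclared component: ", paste(bad, collapse = ", "))
    for (g in names(conditions)) {
      v <- as.integer(conditions[[g]])
      if (!v %in% abn$menus[[g]])
        stop("condition ", v, " is not in the menu of ", g)
      cond[g] <- v
    }
  }
  structure(list(abn = abn, chosen_optional = sel, conditions = cond),
            class = "concrete_network")
}

#' Effective interactions of a concrete network
#'
#' @param net A [concrete_network].
#' @return Data frame of the definite interactions plus the chosen optional
#'   interactions.
#' @export
effective_interactions <- function(net) {
  stopifnot(inherits(net, "concrete_network"))
  ia <- net$abn$interactions
  opt <- which(!ia$definite)
  keep <- ia$definite
  keep[opt[net$chosen_optional]] <- TRUE
  out <- ia[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.concrete_network <- function(x, ...) {
  eff <- effective_interactions(x)
  cat("Concrete Boolean network: ", nrow(x$abn$components), " components, ",
      nrow(eff), " effective interactions (", sum(x$chosen_optional), " of ",
      length(x$chosen_optional), " optional included)\n", sep = "")
  cat("Conditions: ",
      paste0(names(x$conditions), "=", x$conditions, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# canonical identity key of a concretization (for solution-set comparison)
solution_key <- function(net) {
  paste(paste(as.integer(net$chosen_optional), collapse = ""),
        paste(net$conditions, collapse = ","), sep = "|")
}
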