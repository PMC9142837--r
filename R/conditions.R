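# Regulation-condition templates: monotone Boolean update functions over the
# 3x3 occupancy grid (activator level x repressor level, each none/some/all).

#' Occupancy levels
#'
#' Regulator occupancy is summarised on a three-point scale: `"none"` (no
#' regulator of that sign is active, or none is present), `"some"` (at least
#' one but not all are active) and `"all"` (at least one is present and every
#' one is active).
#'
#' @return Character vector `c("none", "some", "all")`, in increasing order.
#' @export
occupancy_levels <- function() c("none", "some", "all")

# cell index (1-based) for activator level a and repressor level r, both 0..2;
# cells are ordered activator-major: (none,none),(none,some),...,(all,all)
.rc_cell <- function(a, r) 3L * a + r + 1L

.rc_level_int <- function(level) {
  if (is.numeric(level)) {
    level <- as.integer(level)
    if (any(level < 0L | level > 2L)) stop("occupancy level out of range")
    return(level)
  }
  m <- match(level, occupancy_levels()) - 1L
  if (anyNA(m)) stop("unknown occupancy level: ", paste(level, collapse = ", "))
  m
}

# all 2^9 tables over the grid, as a 512 x 9 logical matrix
.rc_all_tables <- function() {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 9L))
  m <- as.matrix(grid)
  dimnames(m) <- NULL
  m
}

# monotone: non-decreasing in activator level, non-increasing in repressor level
.rc_is_monotone <- function(tab) {
  for (r in 0:2) {
    col <- tab[.rc_cell(0:2, r)]
    if (is.unsorted(col)) return(FALSE)
  }
  for (a in 0:2) {
    row <- tab[.rc_cell(a, 0:2)]
    if (is.unsorted(rev(row))) return(FALSE)
  }
  TRUE
}

# ON-set of the anchored condition: AllActivators OR (NoRepressors AND NOT NoActivators)
.rc_anchor_table <- function() {
  a <- rep(0:2, each = 3L)
  r <- rep(0:2, times = 3L)
  a == 2L | (r == 0L & a > 0L)
}

.rc_cache <- new.env(parent = emptyenv())

#' The 18 regulation-condition templates
#'
#' Enumerates every Boolean function over the 3x3 occupancy grid that is
#' non-decreasing in the activator level and non-increasing in the repressor
#' level, and drops the two constant functions. Exactly 20 of the 512 grid
#' functions are monotone, so 18 templates remain. They are ordered by a
#' canonical sort of the 9-cell truth table (cells activator-major, each read
#' as a 0/1 string), followed by the one transposition that places the
#' condition "all activators active, or some activators active and no
#' repressor active" at index 5, where the framework's numbering pins it.
#'
#' @return An object of class `regulation_conditions`: an 18 x 9 logical
#'   matrix, one row per condition (row `i` is condition index `i - 1`),
#'   columns the grid cells in canonical order.
#' @examples
#' rc <- regulation_conditions()
#' evaluate_regulation(5, "all", "some")   # TRUE
#' evaluate_regulation(5, "some", "some")  # FALSE
#' @export
regulation_conditions <- function() {
  if (!is.null(.rc_cache$tables)) return(.rc_cache$tables)
  all_tab <- .rc_all_tables()
  keep <- apply(all_tab, 1L, .rc_is_monotone)
  mono <- all_tab[keep, , drop = FALSE]
  nonconst <- mono[rowSums(mono) > 0L & rowSums(mono) < 9L, , drop = FALSE]
  stopifnot(nrow(nonconst) == 18L)
  key <- apply(nonconst, 1L, function(x) paste(as.integer(x), collapse = ""))
  nonconst <- nonconst[order(key), , drop = FALSE]
  anchor <- .rc_anchor_table()
  p <- which(apply(nonconst, 1L, function(x) all(x == anchor)))
  stopifnot(length(p) == 1L)
  if (p != 6L) nonconst[c(6L, p), ] <- nonconst[c(p, 6L), ]
  rownames(nonconst) <- as.character(0:17)
  lv <- occupancy_levels()
  colnames(nonconst) <- paste0("a:", rep(lv, each = 3L), ",r:", rep(lv, 3L))
  class(nonconst) <- c("regulation_conditions", class(nonconst))
  .rc_cache$tables <- nonconst
  nonconst
}

#' Evaluate a regulation condition at an occupancy pair
#'
#' @param condition Condition index in `0..17`, or one row of
#'   [regulation_conditions()].
#' @param activators,repressors Occupancy levels (`"none"`, `"some"`, `"all"`,
#'   or the integers 0..2).
#' @return Logical: the next value the template assigns to the target.
#' @export
evaluate_regulation <- function(condition, activators, repressors) {
  if (length(condition) == 1L && is.numeric(condition)) {
    idx <- as.integer(condition)
    if (idx < 0L || idx > 17L) stop("condition index must be in 0..17")
    tab <- regulation_conditions()[idx + 1L, ]
  } else {
    tab <- as.logical(condition)
    if (length(tab) != 9L) stop("a condition table has 9 cells")
  }
  a <- .rc_level_int(activators)
  r <- .rc_level_int(repressors)
  unname(tab[.rc_cell(a, r)])
}

#' @export
print.regulation_conditions <- function(x, ...) {
  cat("Regulation conditions: 18 monotone non-constant templates",
      "over the activator/repressor occupancy grid\n", sep = " ")
  m <- matrix(as.integer(x), nrow = nrow(x), dimnames = dimnames(unclass(x)))
  print(m)
  invisible(x)
}
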