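#' Health-state labels of the HIV progression model
#'
#' The model uses the WHO four-level clinical staging of HIV disease:
#' `A` (asymptomatic, CD4 > 500 cells/mm3), `B` (symptomatic, CD4 200-500),
#' `C` (AIDS-defining illness, CD4 < 200) and `D` (death, absorbing).
#'
#' @return Character vector `c("A", "B", "C", "D")`.
#' @export
hiv_states <- function() c("A", "B", "C", "D")

#' Alive (non-absorbing) health states
#' @return Character vector `c("A", "B", "C")`.
#' @export
alive_states <- function() c("A", "B", "C")

#' Construct a per-cycle transition matrix
#'
#' Builds and validates a 4x4 row-stochastic matrix of two-month transition
#' probabilities over the states A, B, C, D. Death is absorbing: the D row
#' must be exactly (0, 0, 0, 1).
#'
#' @param x Numeric 4x4 matrix (rows = origin state, columns = destination),
#'   or a length-16 vector filled by row.
#' @param tol Tolerance for row-sum checks (default 1e-9).
#' @return A validated matrix of class `transition_matrix` with dimnames
#'   `A/B/C/D`.
#' @examples
#' m <- transition_matrix(diag(4))
#' @export
transition_matrix <- function(x, tol = 1e-9) {
  if (!is.matrix(x)) {
    if (length(x) != 16L) stop("need a 4x4 matrix or a length-16 vector")
    x <- matrix(as.numeric(x), nrow = 4, byrow = TRUE)
  }
  storage.mode(x) <- "double"
  dimnames(x) <- list(hiv_states(), hiv_states())
  class(x) <- c("transition_matrix", class(x))
  validate_transition_matrix(x, tol = tol)
}

#' Validate a transition matrix
#'
#' Checks that every entry lies in \[0, 1\], that every row sums to one
#' within `tol`, and that the death row is exactly the unit vector on D.
#' Each violation raises a distinct error naming the offending row.
#'
#' @param m 4x4 numeric matrix over states A/B/C/D.
#' @param tol Row-sum tolerance (default 1e-9).
#' @return `m`, unchanged, invisibly classed as `transition_matrix`.
#' @export
validate_transition_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || any(dim(m) != c(4L, 4L)))
    stop("transition matrix must be 4x4 over states A, B, C, D")
  states <- hiv_states()
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("entry out of [0, 1] in row %s (value %.6g)",
                 states[bad[1, 1]], m[bad[1, 1], bad[1, 2]]))
  sums <- rowSums(m)
  off <- which(abs(sums - 1) > tol)
  if (length(off) > 0L)
    stop(sprintf("row %s sums to %.12g, not 1 (tolerance %g)",
                 states[off[1]], sums[off[1]], tol))
  if (!identical(as.numeric(m[4, ]), c(0, 0, 0, 1)))
    stop("row D must be exactly (0, 0, 0, 1): death is absorbing")
  if (!inherits(m, "transition_matrix"))
    class(m) <- c("transition_matrix", class(m))
  m
}

#' Impose a fixed per-cycle death probability on the alive rows
#'
#' Sets the D column of each alive row to `p` and rescales that row's
#' alive-state entries to sum to `1 - p`, preserving their proportions.
#' Used when the background death probability comes from an external
#' source rather than the calibrated matrix.
#'
#' @param m A `transition_matrix`.
#' @param p Per-cycle death probability in \[0, 1).
#' @return A validated `transition_matrix`.
#' @export
apply_death_probability <- function(m, p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p < 1)
  m <- validate_transition_matrix(m)
  for (r in 1:3) {
    alive <- m[r, 1:3]
    s <- sum(alive)
    if (s <= 0) {
      # all mass was on death; spread the survival mass by staying put
      alive <- replace(numeric(3), r, 1)
      s <- 1
    }
    m[r, 1:3] <- alive / s * (1 - p)
    m[r, 4] <- p
  }
  validate_transition_matrix(m)
}

#' Advance a cohort distribution by one cycle
#'
#' Computes the next state-occupancy vector as `dist %*% m`.
#'
#' @param dist Probability vector over A/B/C/D summing to 1.
#' @param m A validated `transition_matrix`.
#' @return Named probability vector over A/B/C/D.
#' @export
step_cohort <- function(dist, m) {
  if (length(dist) != 4L) stop("distribution must have 4 entries (A, B, C, D)")
  if (!is.matrix(m) || any(dim(m) != c(4L, 4L))) stop("matrix must be 4x4")
  out <- as.numeric(dist %*% unclass(m))
  names(out) <- hiv_states()
  out
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("Per-cycle (2-month) transition matrix over HIV stages A/B/C/D\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}
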