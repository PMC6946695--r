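#' Linear/mixed-integer program builder
#'
#' Lightweight builder for the LP and MILP instances used throughout the
#' package (FBA, TFA, FVA, gap-filling, two-condition consistency
#' maximization). Variables are addressed by name; constraints are stored as
#' sparse coefficient lists and assembled into a dense matrix at solve time,
#' which is adequate at the problem sizes this package targets.
#'
#' @return An object of class `lp_problem`.
#' @keywords internal
#' @export
lp_problem <- function() {
  lp <- new.env(parent = emptyenv())
  lp$var_names <- character()
  lp$var_idx <- new.env(parent = emptyenv(), hash = TRUE)
  lp$lb <- numeric()
  lp$ub <- numeric()
  lp$obj <- numeric()
  lp$integer <- logical()
  lp$support <- integer()
  lp$cons <- list()
  lp$n_con <- 0L
  class(lp) <- "lp_problem"
  lp
}

#' Add a variable to an LP problem
#'
#' @param lp an [lp_problem()].
#' @param name unique variable name.
#' @param lb,ub bounds (may be infinite).
#' @param obj objective coefficient.
#' @param integer whether the variable is integer-constrained.
#' @keywords internal
#' @export
lp_add_var <- function(lp, name, lb = -Inf, ub = Inf, obj = 0,
                       integer = FALSE) {
  if (!is.null(lp$var_idx[[name]]))
    stop("duplicate variable name: ", name)
  k <- length(lp$var_names) + 1L
  lp$var_names[k] <- name
  assign(name, k, envir = lp$var_idx)
  lp$lb[k] <- lb
  lp$ub[k] <- ub
  lp$obj[k] <- obj
  lp$integer[k] <- integer
  lp$support[k] <- NA_integer_
  invisible(lp)
}

#' Attach a support variable to an integer indicator
#'
#' Declares that the integer variable behaves as an activity indicator of
#' a continuous variable (1 whenever the support is nonzero), which the
#' branch-and-bound uses to propose verified integer solutions quickly.
#' @param lp an [lp_problem()].
#' @param int_name integer variable name.
#' @param support_name continuous support variable name.
#' @keywords internal
#' @export
lp_set_support <- function(lp, int_name, support_name) {
  i <- lp$var_idx[[int_name]]
  s <- lp$var_idx[[support_name]]
  if (is.null(i) || is.null(s)) stop("unknown variable in lp_set_support")
  lp$support[i] <- s
  invisible(lp)
}

#' Add a linear constraint
#'
#' @param lp an [lp_problem()].
#' @param coefs named numeric vector of coefficients over existing variables.
#' @param sense one of `"<="`, `"="`, `">="`.
#' @param rhs right-hand side.
#' @param name optional constraint label.
#' @keywords internal
#' @export
lp_add_con <- function(lp, coefs, sense = c("<=", "=", ">="), rhs,
                       name = NULL) {
  sense <- match.arg(sense)
  idx <- vapply(names(coefs), function(nm) {
    i <- lp$var_idx[[nm]]
    if (is.null(i)) stop("unknown variable in constraint: ", nm)
    i
  }, integer(1L), USE.NAMES = FALSE)
  lp$n_con <- lp$n_con + 1L
  lp$cons[[lp$n_con]] <- list(idx = idx, val = unname(as.numeric(coefs)),
                              sense = sense, rhs = rhs, name = name)
  invisible(lp)
}

#' Set (replace) objective coefficients by variable name
#' @keywords internal
#' @export
lp_set_objective <- function(lp, coefs, reset = TRUE) {
  if (reset) lp$obj[] <- 0
  for (nm in names(coefs)) {
    i <- lp$var_idx[[nm]]
    if (is.null(i)) stop("unknown variable in objective: ", nm)
    lp$obj[i] <- coefs[[nm]]
  }
  invisible(lp)
}

#' Change bounds of an existing variable
#' @keywords internal
#' @export
lp_set_bounds <- function(lp, name, lb = NULL, ub = NULL) {
  i <- lp$var_idx[[name]]
  if (is.null(i)) stop("unknown variable: ", name)
  if (!is.null(lb)) lp$lb[i] <- lb
  if (!is.null(ub)) lp$ub[i] <- ub
  invisible(lp)
}

#' Solve an LP/MILP problem
#'
#' @param lp an [lp_problem()].
#' @param maximize logical; maximize (default) or minimize.
#' @param max_nodes branch-and-bound node limit.
#' @param time_limit wall-clock limit in seconds (`Inf` = none).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"time_limit"`, `"iteration_limit"`), `objective`, and named solution
#'   vector `x`.
#' @keywords internal
#' @export
lp_solve <- function(lp, maximize = TRUE, max_nodes = 200000L,
                     time_limit = Inf) {
  n <- length(lp$var_names)
  m <- lp$n_con
  A <- matrix(0, nrow = max(m, 1L), ncol = n)
  b <- numeric(max(m, 1L))
  sen <- integer(max(m, 1L))
  if (m > 0L) {
    for (i in seq_len(m)) {
      cn <- lp$cons[[i]]
      A[i, cn$idx] <- A[i, cn$idx] + cn$val
      b[i] <- cn$rhs
      sen[i] <- switch(cn$sense, "<=" = -1L, "=" = 0L, ">=" = 1L)
    }
  } else {
    # degenerate 0-row system; add a vacuous constraint 0 <= 1
    sen[1] <- -1L
    b[1] <- 1
  }
  int_idx <- which(lp$integer) - 1L        # 0-based for C++
  supp <- ifelse(is.na(lp$support), -1L, lp$support - 1L)
  if (!length(supp)) supp <- integer(0)
  r <- .solve_milp_cpp(A, b, sen, lp$obj, lp$lb, lp$ub,
                       as.integer(int_idx), as.integer(supp),
                       maximize = maximize,
                       max_nodes = as.integer(max_nodes),
                       time_limit = if (is.finite(time_limit))
                         as.numeric(time_limit) else -1.0)
  x <- as.numeric(r$x)
  names(x) <- lp$var_names
  list(status = r$status, objective = as.numeric(r$objective), x = x)
}

#' Deep-copy an LP problem
#'
#' `lp_problem` objects are environments; cloning allows derived solves
#' (bound fixing, integer cuts) without mutating the original.
#' @param lp an [lp_problem()].
#' @keywords internal
#' @export
lp_clone <- function(lp) {
  new <- lp_problem()
  new$var_names <- lp$var_names
  for (nm in ls(lp$var_idx))
    assign(nm, lp$var_idx[[nm]], envir = new$var_idx)
  new$lb <- lp$lb
  new$ub <- lp$ub
  new$obj <- lp$obj
  new$integer <- lp$integer
  new$support <- lp$support
  new$cons <- lp$cons
  new$n_con <- lp$n_con
  new
}

#' @exportS3Method base::print
print.lp_problem <- function(x, ...) {
  cat("<lp_problem> ", length(x$var_names), " variables (",
      sum(x$integer), " integer), ", x$n_con, " constraints\n", sep = "")
  invisible(x)
}
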