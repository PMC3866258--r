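# Parameter estimation: pseudo-likelihood with lasso.
#
# The log pseudo-likelihood sums, over instances and cells, the log of the
# local conditional probability of the observed contact state given the
# observed neighbor states:
#
#   L(theta) = sum_n sum_ij log Pr(r_ij^(n) | r_Nij^(n), m^(n), a^(n), b^(n), theta)
#
# Its gradient has the standard "observed minus expected feature" form: for
# each cell, -dU(observed)/dw plus the expectation of dU/dw over the two
# cell states under the local conditional. The fitted objective is
# L(theta) - C (||w_f||_1 + ||w_g||_1), maximized by OWL-QN.

as_instance_list <- function(instances) {
  if (inherits(instances, "rb_instance")) instances <- list(instances)
  stopifnot(length(instances) >= 1L,
            all(vapply(instances, inherits, TRUE, "rb_instance")))
  instances
}

labeled_designs <- function(instances, config) {
  lapply(instances, function(inst) {
    if (is.null(inst$r)) stop("training instances must carry a contact grid")
    build_pll_design(inst, config)
  })
}

#' Training configuration
#'
#' @param lasso_C Nonnegative lasso weight `C` (0 disables the penalty).
#' @param max_iterations Optimizer iteration cap.
#' @param gradient_tolerance Convergence threshold on the (pseudo-)gradient
#'   sup-norm.
#' @param initial_params Optional `rb_params` start point (default zeros;
#'   the per-cell objective is concave, so the start point is immaterial up
#'   to tolerance).
#' @param seed Integer seed for any randomized restarts.
#' @return An `rb_training_config`.
#' @export
training_config <- function(lasso_C = 0, max_iterations = 500L,
                            gradient_tolerance = 1e-5,
                            initial_params = NULL, seed = 1L) {
  stopifnot(lasso_C >= 0, gradient_tolerance > 0, max_iterations >= 1L)
  structure(list(lasso_C = lasso_C, max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance,
                 initial_params = initial_params, seed = as.integer(seed)),
            class = "rb_training_config")
}

#' Log pseudo-likelihood of labeled instances
#'
#' @param params An `rb_params`.
#' @param config An `rb_feature_config`.
#' @param instances A labeled `rb_instance` or list of them.
#' @return Scalar `L(theta)` (always <= 0).
#' @export
pseudo_log_likelihood <- function(params, config, instances) {
  designs <- labeled_designs(as_instance_list(instances), config)
  sum(vapply(designs, pll_design, 0, w_f = params$w_f, w_g = params$w_g))
}

#' Analytic gradient of the log pseudo-likelihood
#'
#' @inheritParams pseudo_log_likelihood
#' @return List with components `w_f` and `w_g`.
#' @export
pll_gradient <- function(params, config, instances) {
  designs <- labeled_designs(as_instance_list(instances), config)
  g <- Reduce(`+`, lapply(designs, pll_grad_design,
                          w_f = params$w_f, w_g = params$w_g))
  list(w_f = g[seq_len(config$f_dim)],
       w_g = g[config$f_dim + seq_len(config$g_dim)])
}

#' Lasso-penalized training objective
#'
#' `L(theta) - C (||w_f||_1 + ||w_g||_1)`; with `C = 0` this is the log
#' pseudo-likelihood itself.
#'
#' @inheritParams pseudo_log_likelihood
#' @param C Nonnegative lasso weight.
#' @return Scalar objective value.
#' @export
crf_objective <- function(params, config, instances, C = 0) {
  stopifnot(C >= 0)
  pseudo_log_likelihood(params, config, instances) -
    C * (sum(abs(params$w_f)) + sum(abs(params$w_g)))
}

#' Fit CRF parameters by penalized pseudo-likelihood
#'
#' Maximizes the lasso-penalized log pseudo-likelihood with the
#' orthant-wise limited-memory quasi-Newton optimizer. With `lasso_C`
#' exceeding every gradient coordinate magnitude at zero, the zero vector
#' is already optimal and is returned exactly.
#'
#' @param instances Labeled `rb_instance` list.
#' @param config An `rb_feature_config`.
#' @param control An `rb_training_config`.
#' @return Fitted `rb_params`, with attributes `objective` (the achieved
#'   penalized objective), `converged`, `iterations` and `trace` (penalized
#'   objective per accepted iterate, non-decreasing).
#' @export
crf_fit <- function(instances, config, control = training_config()) {
  stopifnot(inherits(config, "rb_feature_config"),
            inherits(control, "rb_training_config"))
  instances <- as_instance_list(instances)
  designs <- labeled_designs(instances, config)
  nf <- config$f_dim
  split_theta <- function(theta) {
    list(w_f = theta[seq_len(nf)], w_g = theta[nf + seq_len(config$g_dim)])
  }
  fn <- function(theta) {
    w <- split_theta(theta)
    -sum(vapply(designs, pll_design, 0, w_f = w$w_f, w_g = w$w_g))
  }
  gr <- function(theta) {
    w <- split_theta(theta)
    -Reduce(`+`, lapply(designs, pll_grad_design, w_f = w$w_f, w_g = w$w_g))
  }
  x0 <- if (is.null(control$initial_params)) {
    numeric(nf + config$g_dim)
  } else {
    c(control$initial_params$w_f, control$initial_params$w_g)
  }
  res <- owlqn(fn, gr, x0, C = control$lasso_C,
               max_iter = control$max_iterations,
               tol = control$gradient_tolerance)
  w <- split_theta(res$par)
  out <- crf_params(config, w$w_f, w$w_g)
  attr(out, "objective") <- -res$value
  attr(out, "converged") <- res$converged
  attr(out, "iterations") <- res$iterations
  attr(out, "trace") <- -res$trace
  out
}

#' Serialize / read CRF parameters as JSON
#'
#' The JSON object records the feature family, the grouping name and both
#' weight vectors.
#'
#' @param params An `rb_params`.
#' @param path File path.
#' @return `read_params_json` returns an `rb_params`.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "rb_params"))
  obj <- list(family = params$config$family,
              grouping = as.integer(params$config$grouping$name),
              w_f = params$w_f, w_g = params$w_g)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- feature_config(obj$family, grouping_scheme(obj$grouping))
  crf_params(config, obj$w_f, obj$w_g)
}
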