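# Optimizers over parameter trees: Adam, plain SGD, and the sharpness-aware
# minimization (SAM) wrapper that composes with either.

#' SAM configuration
#'
#' @param enabled use the SAM two-step update.
#' @param rho neighborhood radius of the adversarial weight perturbation
#'   (global L2 normalization over all parameters).
#' @param base base optimizer, `"adam"` or `"sgd"`.
#' @param lr learning rate of the base optimizer.
#' @param beta1,beta2,eps Adam moment coefficients and stabilizer.
#' @param weight_decay L2 coefficient added to the gradient of weight
#'   matrices (leaves named `W`, `W1`, `W2`).
#' @return A list of class `sam_config`.
#' @export
sam_config <- function(enabled = TRUE, rho = 0.05, base = c("adam", "sgd"),
                       lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0) {
  if (rho < 0) abort("`rho` must be >= 0")
  structure(list(enabled = isTRUE(enabled), rho = rho,
                 base = match.arg(base), lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps, weight_decay = weight_decay),
            class = "sam_config")
}

opt_init <- function(params, config) {
  if (config$base == "adam") {
    list(t = 0L,
         m = tree_map(function(x) x * 0, params),
         v = tree_map(function(x) x * 0, params))
  } else {
    list(t = 0L)
  }
}

is_weight_leaf <- function(name) name %in% c("W", "W1", "W2")

apply_weight_decay <- function(grads, params, wd) {
  if (wd <= 0) return(grads)
  tree_map2_named(function(g, w, name) {
    if (is_weight_leaf(name)) g + 2 * wd * w else g
  }, grads, params)
}

opt_step <- function(params, grads, opt_state, config) {
  grads <- apply_weight_decay(grads, params, config$weight_decay)
  if (config$base == "sgd") {
    new_params <- tree_map2(function(w, g) w - config$lr * g, params, grads)
    opt_state$t <- opt_state$t + 1L
    return(list(params = new_params, opt_state = opt_state))
  }
  t <- opt_state$t + 1L
  b1 <- config$beta1; b2 <- config$beta2
  m <- tree_map2(function(mm, g) b1 * mm + (1 - b1) * g, opt_state$m, grads)
  v <- tree_map2(function(vv, g) b2 * vv + (1 - b2) * g^2, opt_state$v, grads)
  bc1 <- 1 - b1^t
  bc2 <- 1 - b2^t
  upd <- tree_map2(function(mm, vv) {
    (mm / bc1) / (sqrt(vv / bc2) + config$eps)
  }, m, v)
  new_params <- tree_map2(function(w, u) w - config$lr * u, params, upd)
  list(params = new_params, opt_state = list(t = t, m = m, v = v))
}

#' One sharpness-aware minimization update
#'
#' Performs the two-step SAM update around any base optimizer:
#' \enumerate{
#'   \item evaluate the gradient \eqn{g_1 = \nabla L(w)} at the current
#'     weights and climb to the adversarial point
#'     \eqn{\tilde w = w + \rho\, g_1 / \|g_1\|_2} (global L2 norm over all
#'     parameters);
#'   \item evaluate \eqn{g_2 = \nabla L(\tilde w)} there and apply the base
#'     optimizer update at the *original* weights `w` using \eqn{g_2}.
#' }
#' Exactly two gradient evaluations are performed per update; the perturbed
#' weights never leak into the next iteration. With `rho = 0`, or when
#' \eqn{\|g_1\| = 0}, the update equals the base optimizer's. When SAM is
#' disabled in the config a single gradient evaluation is used.
#'
#' @param grad_fn function of the parameter tree returning
#'   `list(loss = <scalar>, grads = <tree>)`. It may accept a second logical
#'   argument `final` which is `TRUE` only on the gradient evaluation whose
#'   result feeds the base optimizer (used to update batch-norm statistics
#'   only once per SAM update).
#' @param params parameter tree (nested named list of numerics), or a bare
#'   numeric vector.
#' @param config a [sam_config()].
#' @param opt_state optimizer state from a previous call, or `NULL`.
#' @return `list(params, opt_state, loss, n_grad_evals)`.
#' @export
sam_update <- function(grad_fn, params, config = sam_config(),
                       opt_state = NULL) {
  if (is.null(opt_state)) opt_state <- opt_init(params, config)
  gf <- function(w, final) {
    r <- if (length(formals(grad_fn)) >= 2) grad_fn(w, final) else grad_fn(w)
    if (!tree_finite(r$grads)) {
      abort("non-finite gradient encountered; update aborted",
            class = "pkdseg_nonfinite_grad")
    }
    r
  }
  if (!config$enabled) {
    r <- gf(params, TRUE)
    st <- opt_step(params, r$grads, opt_state, config)
    return(list(params = st$params, opt_state = st$opt_state, loss = r$loss,
                n_grad_evals = 1L))
  }
  r1 <- gf(params, FALSE)
  nrm <- tree_global_norm(r1$grads)
  w_adv <- if (config$rho > 0 && nrm > 0) {
    scale <- config$rho / nrm
    tree_map2(function(w, g) w + scale * g, params, r1$grads)
  } else {
    params
  }
  r2 <- gf(w_adv, TRUE)
  st <- opt_step(params, r2$grads, opt_state, config)
  list(params = st$params, opt_state = st$opt_state, loss = r1$loss,
       n_grad_evals = 2L)
}
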