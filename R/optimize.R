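# Levenberg-Marquardt refinement of nodal activation times with
# surface-Laplacian regularization:
#   argmin_delta  ||V - phi(delta)||_F^2 + mu^2 ||L delta||_F^2

#' Optimizer settings
#'
#' @param mu2 regularization weight on the squared Frobenius norm of the
#'   surface Laplacian of the activation times; default `5e-6`
#'   (mV^2 ms^2 m^-2) -- deliberately very small, chosen so the refined
#'   sequence keeps realistic smoothness without being dominated by the
#'   penalty.
#' @param max_iterations LM iteration cap, default 25.
#' @param lambda_init,lambda_factor initial damping and its multiplicative
#'   update (divide on accept, multiply on reject).
#' @param tol relative objective-decrease convergence threshold, default 1e-4.
#' @param step_max trust bound on a single update of any node (ms); steps
#'   beyond it are rejected and the damping increased.
#' @return list of settings.
#' @export
optimizer_settings <- function(mu2 = 5e-6, max_iterations = 25,
                               lambda_init = 1e-3, lambda_factor = 10,
                               tol = 1e-4, step_max = 25) {
  stopifnot(mu2 >= 0, max_iterations >= 1, lambda_init > 0,
            lambda_factor > 1, tol > 0, step_max > 0)
  list(mu2 = mu2, max_iterations = max_iterations,
       lambda_init = lambda_init, lambda_factor = lambda_factor, tol = tol,
       step_max = step_max)
}

# computed BSPM matrix (electrodes x samples), average referenced
phi_of_delta <- function(CA, lat, wf, ts) {
  S <- wf$s(outer(-lat, ts, "+"))
  CA %*% S
}

#' Levenberg-Marquardt activation-time refinement
#'
#' Iteratively minimizes
#' `||V - phi(delta)||_F^2 + mu^2 ||L delta||_F^2` over the nodal
#' activation times.  The Jacobian is analytic: column `n` is the outer
#' product of column `n` of the (average-referenced) transfer matrix with
#' the waveform-upstroke derivative at `t - delta_n`; its Gram matrix
#' factorizes into an elementwise product of two small Gram matrices, which
#' keeps each iteration at `O(N^2 (E + T))`.  Steps are accepted only when
#' the objective decreases, so the accepted-step objective is monotone
#' non-increasing.
#'
#' @param seq0 initial [activation_sequence()] (or numeric LAT vector).
#' @param tm a [build_transfer_matrix()] result.
#' @param wf a [tmp_waveform()].
#' @param recorded QRS-windowed [bspm()] (the target `V`).
#' @param L surface Laplacian from [surface_laplacian()] on the source mesh.
#' @param settings an [optimizer_settings()] list.
#' @param numeric_jacobian use a finite-difference Jacobian instead of the
#'   analytic one (testing aid), default `FALSE`.
#' @return list with `sequence` (refined [activation_sequence()]),
#'   `iterations` (accepted LM iterations), `converged`, and `log`
#'   (data frame: iteration, objective, lambda, accepted).
#' @export
optimize_lat <- function(seq0, tm, wf, recorded, L,
                         settings = optimizer_settings(),
                         numeric_jacobian = FALSE) {
  lat <- if (inherits(seq0, "activation_sequence")) seq0$lat else
    as.numeric(seq0)
  N <- ncol(tm$A)
  if (length(lat) != N) stop("seq0 does not match the transfer matrix")
  if (nrow(L) != N || ncol(L) != N) stop("L does not match the source mesh")
  rt <- recorded_times(recorded)
  ts <- rt$t
  V <- recorded$potentials
  E <- nrow(tm$A)
  C <- diag(E) - 1 / E # average-reference projector
  CA <- C %*% tm$A
  CtC <- crossprod(CA) # N x N, cached
  L <- as(L, "CsparseMatrix")
  LtL <- Matrix::crossprod(L)
  mu2 <- settings$mu2

  objective <- function(lat) {
    R <- V - phi_of_delta(CA, lat, wf, ts)
    reg <- as.numeric(L %*% lat)
    sum(R^2) + mu2 * sum(reg^2)
  }

  lambda <- settings$lambda_init
  obj <- objective(lat)
  log <- data.frame(iteration = 0L, objective = obj, lambda = lambda,
                    accepted = TRUE)
  converged <- FALSE
  iter <- 0L
  while (iter < settings$max_iterations) {
    iter <- iter + 1L
    Ds <- wf$ds(outer(ts, lat, "-")) # T x N, ds(t - delta_n)
    R <- V - phi_of_delta(CA, lat, wf, ts)
    if (!all(is.finite(R))) stop("non-finite residual at iteration ", iter)
    if (numeric_jacobian) {
      h <- 1e-4
      J <- matrix(0, E * length(ts), N)
      for (n in seq_len(N)) {
        lp <- lat; lp[n] <- lp[n] + h
        lm_ <- lat; lm_[n] <- lm_[n] - h
        J[, n] <- as.vector(phi_of_delta(CA, lp, wf, ts) -
                              phi_of_delta(CA, lm_, wf, ts)) / (2 * h)
      }
      H <- crossprod(J)
      g <- as.numeric(crossprod(J, as.vector(R)))
    } else {
      # d phi / d delta_n = -CA[, n] ds_n(t): JtJ = CtC * (Ds' Ds),
      # Jtr = -rowSums((CA' R) * Ds')
      H <- CtC * crossprod(Ds)
      g <- -rowSums(crossprod(CA, R) * t(Ds))
    }
    # gradient of the full objective is -2(J' r) + 2 mu2 L'L delta; LM solves
    # (H + mu2 L'L + lambda diag(H)) step = (J' r) - mu2 L'L delta
    rhs <- g - mu2 * as.numeric(LtL %*% lat)
    accepted <- FALSE
    for (try in 1:25) {
      Haug <- H + mu2 * as.matrix(LtL)
      # damping floored at a fraction of the largest curvature so that
      # near-null directions (nodes barely visible at the electrodes)
      # cannot produce runaway steps
      damp <- pmax(diag(H), 1e-3 * max(diag(H)), 1e-12)
      diag(Haug) <- diag(Haug) + lambda * damp
      step <- tryCatch(solve(Haug, rhs), error = function(e) NULL)
      if (!is.null(step) && max(abs(step)) > settings$step_max) step <- NULL
      if (!is.null(step)) {
        trial <- lat + step
        obj_trial <- objective(trial)
        if (is.finite(obj_trial) && obj_trial < obj) {
          lat <- trial
          rel <- (obj - obj_trial) / max(obj, .Machine$double.eps)
          obj <- obj_trial
          lambda <- lambda / settings$lambda_factor
          accepted <- TRUE
          log <- rbind(log, data.frame(iteration = iter, objective = obj,
                                       lambda = lambda, accepted = TRUE))
          if (rel < settings$tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * settings$lambda_factor
    }
    if (!accepted) { # no downhill step found: local optimum
      converged <- TRUE
      log <- rbind(log, data.frame(iteration = iter, objective = obj,
                                   lambda = lambda, accepted = FALSE))
    }
    if (converged) break
  }
  list(sequence = activation_sequence(lat,
                                      if (inherits(seq0, "activation_sequence"))
                                        seq0$foci else list()),
       iterations = iter, converged = converged, log = log)
}
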