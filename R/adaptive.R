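#' Construct a prototype bank
#'
#' The adaptive layer's perceptual learning system is a bank of up to
#' \code{K} prototype vectors updated by a local delta rule. The active
#' prototype is the nearest one; its distance to the percept is the
#' reconstruction error. Prototypes are initialized from the first \code{K}
#' distinct percepts encountered, so learning is deterministic.
#'
#' @param K maximum number of prototypes, >= 1.
#' @param m percept dimension.
#' @param alpha prototype learning rate in (0, 1].
#' @param init_tol a percept farther than this from every stored prototype
#'   recruits a free slot.
#' @return an object of class \code{prototype_bank}.
#' @export
prototype_bank <- function(K, m, alpha = 0.1, init_tol = 1e-6) {
  stopifnot(K >= 1, alpha > 0, alpha <= 1)
  structure(list(mu = matrix(numeric(0), nrow = 0, ncol = m),
                 K = as.integer(K), m = as.integer(m), alpha = alpha,
                 init_tol = init_tol, usage = integer(0),
                 last_used = integer(0), tick = 0L),
            class = "prototype_bank")
}

#' Nearest-prototype perception
#'
#' Finds the prototype minimizing Euclidean distance to the percept (ties to
#' the lowest index) and returns the reconstruction error.
#'
#' @param bank a [prototype_bank()] with at least one stored prototype.
#' @param x percept vector of dimension \code{bank$m}.
#' @return \code{list(k, eps)}.
#' @export
perceive <- function(bank, x) {
  if (length(x) != bank$m) stop("perceive: percept dimension mismatch")
  if (nrow(bank$mu) == 0L) stop("perceive: empty prototype bank")
  d2 <- rowSums((bank$mu - rep(x, each = nrow(bank$mu)))^2)
  k <- which.min(d2)
  list(k = k, eps = sqrt(d2[k]))
}

#' Delta-rule prototype update
#'
#' Moves the winning prototype a fraction \code{alpha} toward the percept
#' and increments its usage count; all other prototypes are unchanged.
#'
#' @param bank a [prototype_bank()].
#' @param x percept vector.
#' @param k winning prototype index.
#' @return the updated bank.
#' @export
update_prototypes <- function(bank, x, k) {
  stopifnot(k >= 1, k <= nrow(bank$mu))
  bank$mu[k, ] <- bank$mu[k, ] + bank$alpha * (x - bank$mu[k, ])
  bank$usage[k] <- bank$usage[k] + 1L
  bank
}

# Recruit a slot for a sufficiently novel percept (farther than the
# vigilance radius from every prototype); when the bank is full, the
# least-recently-used slot is recycled (resource-allocating quantization),
# which keeps prototypes in active service — including heavily reinforced
# ones — stable across context switches.
# Returns list(bank, k, eps, new).
bank_observe <- function(bank, x) {
  bank$tick <- bank$tick + 1L
  if (nrow(bank$mu) == 0L) {
    bank$mu <- matrix(x, nrow = 1)
    bank$usage <- 1L
    bank$last_used <- bank$tick
    return(list(bank = bank, k = 1L, eps = 0, new = TRUE))
  }
  p <- perceive(bank, x)
  if (p$eps > bank$init_tol) {
    if (nrow(bank$mu) < bank$K) {
      bank$mu <- rbind(bank$mu, x)
      bank$usage <- c(bank$usage, 1L)
      bank$last_used <- c(bank$last_used, bank$tick)
      return(list(bank = bank, k = nrow(bank$mu), eps = p$eps, new = TRUE))
    }
    j <- which.min(bank$last_used)
    bank$mu[j, ] <- x
    bank$usage[j] <- 1L
    bank$last_used[j] <- bank$tick
    return(list(bank = bank, k = j, eps = p$eps, new = TRUE))
  }
  bank$last_used[p$k] <- bank$tick
  list(bank = bank, k = p$k, eps = p$eps, new = FALSE)
}

#' Update the time-averaged reconstruction error
#'
#' Exponential smoothing \code{eps_bar <- (1 - lambda) * eps_bar + lambda *
#' eps}. The running average is the short-term-memory acquisition threshold
#' of the contextual layer.
#'
#' @param ea \code{list(eps_bar, lambda)} with \code{lambda} in (0, 1].
#' @param eps current reconstruction error, >= 0.
#' @return the updated average.
#' @export
update_error_average <- function(ea, eps) {
  stopifnot(eps >= 0)
  ea$eps_bar <- (1 - ea$lambda) * ea$eps_bar + ea$lambda * eps
  ea
}

#' Delta-rule valence update (classical conditioning)
#'
#' When an unconditioned stimulus is present, the active prototype's value
#' moves toward the US valence: \code{u <- u + eta * (US - u)} — the
#' Rescorla-Wagner acquisition step for a single stimulus. When the
#' conditioned stimulus occurs alone, the value extinguishes toward zero at
#' the same rate.
#'
#' @param w \code{list(u, eta)}: per-prototype values and learning rate.
#' @param k active prototype index.
#' @param us_valence signed US magnitude.
#' @param us_present logical; \code{FALSE} is an extinction step.
#' @return the updated weights.
#' @export
update_value <- function(w, k, us_valence, us_present = TRUE) {
  stopifnot(k >= 1, k <= length(w$u))
  target <- if (us_present) us_valence else 0
  w$u[k] <- w$u[k] + w$eta * (target - w$u[k])
  w
}

#' Conditioned-response shaping of the reactive action
#'
#' When the absolute value estimate of the active prototype reaches the CR
#' threshold, the adaptive layer emits a conditioned response: an egocentric
#' turn toward (positive value) or away from (negative value) the stimulus
#' bearing, at speed \code{v_max * min(1, |v|)}. The CR replaces the
#' reactive action when the adaptive strength exceeds the reactive strength,
#' and otherwise contributes an additive turn bias with weight
#' \code{|v| / (|v| + strength_rl)}. Below threshold the reactive action
#' passes through unchanged.
#'
#' @param v_hat value estimate of the active prototype.
#' @param bearing stimulus bearing relative to the agent's heading (radians),
#'   or \code{NULL}/\code{NA} when no stimulus is in view.
#' @param rl_action the reactive layer's action.
#' @param strength_rl the reactive winner's strength.
#' @param theta_cr CR threshold.
#' @param v_max speed ceiling.
#' @return \code{list(action, replaced)}; \code{replaced} is \code{TRUE} when
#'   the CR displaced the reactive action.
#' @export
shape_response <- function(v_hat, bearing, rl_action, strength_rl,
                           theta_cr = 0.1, v_max = 0.5) {
  if (is.null(bearing) || is.na(bearing) || abs(v_hat) < theta_cr) {
    return(list(action = rl_action, replaced = FALSE))
  }
  cr_turn <- if (v_hat > 0) wrap_angle(bearing) else wrap_angle(bearing + pi)
  strength_al <- abs(v_hat)
  if (strength_al > strength_rl) {
    act <- action("egocentric", turn = cr_turn,
                  speed = v_max * min(1, strength_al))
    return(list(action = act, replaced = TRUE))
  }
  wgt <- strength_al / (strength_al + strength_rl)
  act <- rl_action
  act$turn <- wrap_angle(rl_action$turn + wgt * wrap_angle(cr_turn - rl_action$turn))
  list(action = act, replaced = FALSE)
}

# Fresh adaptive-layer state bundle.
al_state <- function(K, m, alpha, eta, lambda, theta_cr, eps_bar0 = 0.5) {
  list(bank = prototype_bank(K, m, alpha),
       w = list(u = numeric(0), eta = eta),
       ea = list(eps_bar = eps_bar0, lambda = lambda),
       theta_cr = theta_cr)
}

# One adaptive-layer observation: recruit/perceive, extend value slots,
# update prototype and error average. Returns state plus the step's
# k, eps, qualifies flag (eps below the pre-update average) and v_hat.
al_observe <- function(al, x) {
  qual_threshold <- al$ea$eps_bar
  ob <- bank_observe(al$bank, x)
  al$bank <- ob$bank
  if (length(al$w$u) < nrow(al$bank$mu)) {
    al$w$u <- c(al$w$u, numeric(nrow(al$bank$mu) - length(al$w$u)))
  }
  if (ob$new) al$w$u[ob$k] <- 0 # recycled slots forget their valence
  if (!ob$new) al$bank <- update_prototypes(al$bank, x, ob$k)
  al$ea <- update_error_average(al$ea, ob$eps)
  list(al = al, k = ob$k, eps = ob$eps,
       qualifies = ob$eps < qual_threshold,
       v_hat = al$w$u[ob$k])
}
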