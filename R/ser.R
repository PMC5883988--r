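#' SER model parameters
#'
#' The four dynamical parameters of the agent model: `sop`, the probability
#' that a susceptible node fires spontaneously when its neighbor fields do
#' not force the outcome; `nep`, the probability that a refractory node
#' recovers to susceptible at a step; and the thresholds `pi_p` / `pi_n`
#' applied to the average activity of positively / negatively linked
#' neighbors before binarization.
#'
#' @param sop,nep,pi_p,pi_n probabilities/thresholds in `[0, 1]`.
#' @return an object of class `ser_params`.
#' @export
ser_params <- function(sop, nep, pi_p, pi_n = pi_p) {
  v <- c(sop = sop, nep = nep, pi_p = pi_p, pi_n = pi_n)
  if (!is.numeric(v) || length(v) != 4L || anyNA(v) || any(v < 0) || any(v > 1))
    stop("all SER parameters must lie in [0, 1]")
  structure(as.list(v), class = "ser_params")
}

#' @export
print.ser_params <- function(x, ...) {
  cat(sprintf("<ser_params> sop=%g nep=%g pi_p=%g pi_n=%g\n",
              x$sop, x$nep, x$pi_p, x$pi_n))
  invisible(x)
}

# Integer state codes used internally.
SER_S <- 1L
SER_E <- 2L
SER_R <- 3L

#' @rdname ser_params
#' @param states integer vector of state codes.
#' @export
ser_state_labels <- function(states) c("S", "E", "R")[states]

#' Per-agent binary fields
#'
#' Computes the three binary variables that drive the transition rules:
#' `phi_s` flags susceptible nodes; `phi_p` (`phi_n`) is 1 when the fraction
#' of excited nodes among a node's positively (negatively) linked neighbors
#' reaches the threshold `pi_p` (`pi_n`). A node with no neighbors of a sign
#' has average 0 for that sign, so its field is 0 whenever the threshold is
#' positive. The comparison is non-strict (`>=`) by default so that a
#' threshold of 1 remains attainable; `strict = TRUE` switches to `>`.
#'
#' @param states integer vector of state codes (see [ser_simulate()]).
#' @param network a `signed_network`.
#' @param params a [ser_params()].
#' @param strict logical; use strict `>` threshold comparison.
#' @return list with binary vectors `phi_s`, `phi_p`, `phi_n` and the raw
#'   neighbor averages `avg_p`, `avg_n`.
#' @export
local_fields <- function(states, network, params, strict = FALSE) {
  n <- nrow(network)
  if (length(states) != n)
    stop("state vector length (", length(states),
         ") does not match network size (", n, ")")
  excited <- as.numeric(states == SER_E)
  pos <- unclass(network) > 0L
  neg <- unclass(network) < 0L
  deg_p <- rowSums(pos)
  deg_n <- rowSums(neg)
  avg_p <- as.numeric(pos %*% excited) / pmax(unname(deg_p), 1)
  avg_n <- as.numeric(neg %*% excited) / pmax(unname(deg_n), 1)
  avg_p[deg_p == 0] <- 0
  avg_n[deg_n == 0] <- 0
  cmp <- if (strict) `>` else `>=`
  list(phi_s = as.integer(states == SER_S),
       phi_p = as.integer(cmp(avg_p, params$pi_p)),
       phi_n = as.integer(cmp(avg_n, params$pi_n)),
       avg_p = avg_p, avg_n = avg_n)
}

#' One synchronous transition step
#'
#' Applies the rule table to every node at once. Excited nodes always become
#' refractory; refractory nodes recover to susceptible with probability
#' `nep`. A susceptible node is excited deterministically when only its
#' positive field is on (`phi_p = 1, phi_n = 0`), is held susceptible when
#' only its negative field is on (`phi_p = 0, phi_n = 1`), and otherwise
#' (fields agreeing, both on or both off) fires spontaneously with
#' probability `sop`.
#'
#' Draws come from the current R random stream; seed control lives in
#' [ser_simulate()].
#'
#' @param states integer state-code vector.
#' @param fields fields from [local_fields()] computed on `states`.
#' @param params a [ser_params()].
#' @return integer state-code vector after the step.
#' @export
ser_transition <- function(states, fields, params) {
  if (!identical(fields$phi_s, as.integer(states == SER_S)))
    stop("fields inconsistent with states: phi_s does not match S membership")
  n <- length(states)
  nxt <- states
  u <- stats::runif(n)

  nxt[states == SER_E] <- SER_R
  isR <- states == SER_R
  nxt[isR] <- ifelse(u[isR] < params$nep, SER_S, SER_R)

  isS <- states == SER_S
  forced_on <- fields$phi_p == 1L & fields$phi_n == 0L
  forced_off <- fields$phi_p == 0L & fields$phi_n == 1L
  spont <- isS & !forced_on & !forced_off
  nxt[isS & forced_on] <- SER_E
  nxt[isS & forced_off] <- SER_S
  nxt[spont] <- ifelse(u[spont] < params$sop, SER_E, SER_S)
  nxt
}

#' Run a full SER simulation
#'
#' Initial states are drawn uniformly at random over \{S, E, R\} per node
#' (unless `init_states` is supplied), then `n_steps` synchronous updates
#' are applied, recording the binary activity (1 = excited) after each
#' update. The same seed always reproduces the same raster; the caller's
#' RNG state is left untouched.
#'
#' @param network a `signed_network`; a network with no links gives
#'   uncoupled dynamics where every node follows the independent
#'   S -(sop)-> E -> R -(nep)-> S cycle.
#' @param params a [ser_params()].
#' @param n_steps number of recorded steps (the standard protocol uses 200).
#' @param seed integer seed for this replicate.
#' @param init_states optional integer state-code vector used instead of the
#'   random initial condition.
#' @param strict passed to [local_fields()].
#' @return a `ser_raster`: binary matrix of `n_steps` rows x regions
#'   columns, with `params` and `seed` attributes.
#' @export
ser_simulate <- function(network, params, n_steps = 200L, seed = 1L,
                         init_states = NULL, strict = FALSE) {
  stopifnot(inherits(params, "ser_params"))
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L)
    stop("n_steps must be a positive integer")
  n <- nrow(network)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  states <- if (is.null(init_states)) {
    sample(c(SER_S, SER_E, SER_R), n, replace = TRUE)
  } else {
    stopifnot(length(init_states) == n, all(init_states %in% 1:3))
    as.integer(init_states)
  }
  raster <- matrix(0L, n_steps, n,
                   dimnames = list(NULL, rownames(network)))
  for (t in seq_len(n_steps)) {
    fields <- local_fields(states, network, params, strict = strict)
    states <- ser_transition(states, fields, params)
    raster[t, ] <- as.integer(states == SER_E)
  }
  structure(raster, params = params, seed = seed,
            class = c("ser_raster", "matrix", "array"))
}

#' @export
print.ser_raster <- function(x, ...) {
  cat("<ser_raster> ", nrow(x), " steps x ", ncol(x), " regions; ",
      sprintf("%.1f%%", 100 * mean(x)), " excited (seed ",
      attr(x, "seed"), ")\n", sep = "")
  invisible(x)
}

#' Stationary occupancy of the uncoupled SER cycle
#'
#' With no links the per-node chain is S -(sop)-> E -> R -(nep)-> S, whose
#' stationary distribution is `p_S = 1 / (1 + sop + sop/nep)`,
#' `p_E = sop * p_S`, `p_R = (sop/nep) * p_S`. Used as the analytic check of
#' the engine in the zero-coupling limit.
#'
#' @param sop,nep probabilities in `(0, 1]`.
#' @return named numeric vector `c(S=, E=, R=)`.
#' @export
ser_uncoupled_stationary <- function(sop, nep) {
  stopifnot(sop > 0, nep > 0)
  pS <- 1 / (1 + sop + sop / nep)
  c(S = pS, E = sop * pS, R = (sop / nep) * pS)
}
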