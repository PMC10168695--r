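# Five-state kinetic scheme of gating plus open-channel block:
#   C  closed, unbound by blocker
#   O  open (conducting)
#   D  desensitized
#   OB open-blocked (blocker in the pore, non-conducting)
#   CB closed-blocked ("trapped": channel closed around the blocker)
#
# Transitions (rates in ms^-1, piecewise constant within a protocol segment):
#   C  -> O   beta * glu           O  -> C   alpha
#   O  -> D   delta(V)             D  -> O   gamma
#   O  -> OB  kon(V)               OB -> O   koff(V) + kperm(V)
#   OB -> CB  alpha * (1 - glu)    CB -> C   trap_unblock_rate
#   C  -> CB  closed_block_factor * kon(V)
#
# Closure of a blocked channel on glutamate removal traps the blocker; the
# trapped pool recovers with time constant 1 / trap_unblock_rate, which is
# what produces the slow component of paired-pulse recovery at depolarized
# potentials.

KINETIC_STATES <- c("C", "O", "D", "OB", "CB")

delta_at <- function(gating, vm) {
  if (is.infinite(gating$delta_evolt)) gating$delta else gating$delta * exp(-vm / gating$delta_evolt)
}

#' Transition-rate matrix of the gating/block scheme
#'
#' Generator matrix `Q` such that `dx/dt = Q x` for the state probability
#' vector `x = (C, O, D, OB, CB)`, at fixed voltage and glutamate occupancy.
#' Columns sum to zero, so total probability is conserved exactly.
#'
#' @param gating A [gating_params()] object.
#' @param block A [block_params()] object.
#' @param vm Membrane potential (mV).
#' @param glu Glutamate occupancy in `[0, 1]`.
#' @return A 5 x 5 rate matrix (ms^-1) with dimnames `C, O, D, OB, CB`.
#' @export
rate_matrix <- function(gating, block, vm, glu) {
  r <- block_rates(block, vm)
  del <- delta_at(gating, vm)
  Q <- matrix(0, 5, 5, dimnames = list(KINETIC_STATES, KINETIC_STATES))
  add <- function(from, to, rate) {
    Q[to, from] <<- Q[to, from] + rate
    Q[from, from] <<- Q[from, from] - rate
  }
  add("C", "O", gating$beta * glu)
  add("O", "C", gating$alpha)
  add("O", "D", del)
  add("D", "O", gating$gamma)
  add("O", "OB", r$kon)
  add("OB", "O", r$koff + r$kperm)
  add("OB", "CB", gating$alpha * (1 - glu))
  add("C", "CB", block$closed_block_factor * r$kon)
  add("CB", "C", block$trap_unblock_rate)
  Q
}

# Dense matrix exponential by scaling and squaring with a Taylor core; only
# used as a fallback when the eigendecomposition of Q is ill-conditioned.
mat_exp <- function(A) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps))) + 1L)
  A <- A / 2^s
  E <- diag(nrow(A))
  term <- E
  for (k in 1:16) {
    term <- term %*% A / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

#' Propagate state probabilities under a constant rate matrix
#'
#' Computes `x(t) = exp(Q t) x0` for every requested time, via the
#' eigendecomposition of `Q` (exact for piecewise-constant rates). Falls back
#' to scaling-and-squaring stepping if `Q` is numerically defective.
#'
#' @param Q Generator matrix from [rate_matrix()].
#' @param x0 Initial state probability vector.
#' @param times Times (ms, relative, non-negative) at which states are wanted.
#' @return Matrix with one column per time and one row per state.
#' @export
propagate_states <- function(Q, x0, times) {
  n <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- !is.null(eg) && all(is.finite(eg$values))
  if (ok) {
    Vv <- eg$vectors
    c0 <- tryCatch(solve(Vv, as.complex(x0)), error = function(e) NULL)
    ok <- !is.null(c0)
  }
  if (ok) {
    ew <- exp(outer(eg$values, times)) # n x length(times)
    out <- Re(Vv %*% (ew * c0))
    colsum <- colSums(out)
    if (max(abs(colsum - 1)) <= 1e-8 && min(out) >= -1e-8 && max(out) <= 1 + 1e-8) {
      rownames(out) <- rownames(Q)
      return(out)
    }
  }
  # fallback: stepwise propagation on the (sorted, unique) time grid
  o <- order(times)
  ts <- times[o]
  out <- matrix(NA_real_, n, length(times), dimnames = list(rownames(Q), NULL))
  x <- x0
  tprev <- 0
  for (i in seq_along(ts)) {
    dt <- ts[i] - tprev
    if (dt > 0) x <- mat_exp(Q * dt) %*% x
    out[, o[i]] <- x
    tprev <- ts[i]
  }
  colsum <- colSums(out)
  if (max(abs(colsum - 1)) > 1e-8 || min(out) < -1e-8 || max(out) > 1 + 1e-8) {
    stop("integration-failure: state probabilities left [0, 1] beyond tolerance")
  }
  out
}

# Piecewise-constant simulation helper shared by step and paired-pulse
# protocols. Segments are (t_start, t_end, glu); returns states at every
# sample time plus the exact state at the end of the last segment.
run_segments <- function(gating, block, vm, segments, x0, times) {
  states <- matrix(NA_real_, 5, length(times), dimnames = list(KINETIC_STATES, NULL))
  x <- x0
  for (s in seq_len(nrow(segments))) {
    t0 <- segments$t_start[s]
    t1 <- segments$t_end[s]
    Q <- rate_matrix(gating, block, vm, segments$glu[s])
    idx <- which(times >= t0 - 1e-9 & times < t1 - 1e-9)
    rel <- c(times[idx] - t0, t1 - t0)
    st <- propagate_states(Q, x, rel)
    if (length(idx)) states[, idx] <- st[, seq_along(idx), drop = FALSE]
    x <- st[, length(rel)]
  }
  # samples at/after the final boundary (if any) hold the terminal state
  tail_idx <- which(times >= segments$t_end[nrow(segments)] - 1e-9)
  if (length(tail_idx)) states[, tail_idx] <- x
  list(states = states, terminal = x)
}

#' Simulate a fast glutamate application (step response)
#'
#' Integrates the five-state gating/block scheme at a fixed holding potential
#' with a square glutamate pulse (`proto$glu_onset` to `proto$glu_onset +
#' proto$pulse_length`). The current is
#' `g_max * rho(V) * P(O) * (V - v_rev)` plus Gaussian baseline noise.
#'
#' @param gating A [gating_params()] object.
#' @param block A [block_params()] object.
#' @param proto A [protocol_spec()] with `kind = "step"`.
#' @param vm Holding potential (mV); defaults to `proto$hold_voltages[1]`.
#' @param init_state Initial state probabilities (default: all channels
#'   closed and unblocked, as after a conditioning pulse at a hyperpolarized
#'   potential that relieves the block).
#' @return A [new_sweep()] with the state trajectory attached as `$states`.
#' @export
simulate_step_response <- function(gating, block, proto, vm = proto$hold_voltages[1],
                                   init_state = c(1, 0, 0, 0, 0)) {
  if (proto$kind != "step") stop("protocol-mismatch: proto$kind must be 'step'")
  stopifnot(length(init_state) == 5, abs(sum(init_state) - 1) < 1e-8)
  if (!is.null(proto$seed)) set.seed(proto$seed)
  dt <- 1 / proto$sample_rate
  times <- seq(0, proto$duration - dt / 2, by = dt)
  t_on <- proto$glu_onset
  t_off <- proto$glu_onset + proto$pulse_length
  segments <- data.frame(
    t_start = c(0, t_on, t_off),
    t_end = c(t_on, t_off, proto$duration),
    glu = c(0, 1, 0)
  )
  segments <- segments[segments$t_end > segments$t_start, , drop = FALSE]
  res <- run_segments(gating, block, vm, segments, init_state, times)
  i <- gating$g_max * orect_factor(gating, vm) * res$states["O", ] * (vm - gating$v_rev)
  if (proto$noise_sd > 0) i <- i + stats::rnorm(length(i), 0, proto$noise_sd)
  new_sweep(
    times, i, vm,
    meta = list(
      kind = "step", hold_mV = vm, sample_rate = proto$sample_rate,
      glu_onset = t_on, pulse_length = proto$pulse_length,
      concentration_uM = block$concentration, seed = proto$seed
    ),
    states = res$states
  )
}

#' Simulate a paired-pulse recovery protocol
#'
#' Two identical glutamate applications separated by each requested
#' inter-pulse interval (gap between the end of pulse 1 and the start of
#' pulse 2). The state at the end of the first sweep is carried through the
#' gap analytically, so trapped-block and desensitized pools relax exactly.
#'
#' @inheritParams simulate_step_response
#' @param proto A [protocol_spec()] with `kind = "paired_pulse"`; intervals
#'   are taken from `proto$inter_pulse_intervals`.
#' @return A list with one element per interval:
#'   `list(interval_ms, sweep1, sweep2)`.
#' @export
simulate_paired_pulse <- function(gating, block, proto, vm = proto$hold_voltages[1]) {
  if (proto$kind != "paired_pulse") stop("protocol-mismatch: proto$kind must be 'paired_pulse'")
  step_proto <- proto
  step_proto$kind <- "step"
  tail_ms <- proto$duration - proto$glu_onset - proto$pulse_length
  if (tail_ms < 0) stop("protocol-mismatch: duration shorter than glu_onset + pulse_length")
  if (!is.null(proto$seed)) set.seed(proto$seed)
  step_proto$seed <- NULL # one stream for the whole train
  lapply(proto$inter_pulse_intervals, function(ivl) {
    gap_free <- ivl - tail_ms - proto$glu_onset
    if (gap_free < 0) {
      stop("protocol-mismatch: interval ", ivl, " ms shorter than the sweep tail + baseline")
    }
    s1 <- simulate_step_response(gating, block, step_proto, vm)
    x <- s1$states[, ncol(s1$states)]
    if (gap_free > 0) {
      Q <- rate_matrix(gating, block, vm, 0)
      x <- propagate_states(Q, x, gap_free)[, 1]
    }
    s2 <- simulate_step_response(gating, block, step_proto, vm, init_state = x)
    list(interval_ms = ivl, sweep1 = s1, sweep2 = s2)
  })
}
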