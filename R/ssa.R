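#' Exact stochastic simulation of the gene-expression model
#'
#' Runs the direct-method Gillespie stochastic simulation algorithm on the
#' two-state-promoter model with reversible mRNA 5'UTR folding. The reaction
#' network is
#' \preformatted{
#'   D0 -> D1          k_on          D1 -> D0          k_off
#'   D1 -> D1 + R_u    v_tx          R_u -> R_f        k_fold
#'   R_f -> R_u        k_unfold      R_u -> R_u + P    k_tl
#'   R_f -> R_f + P    k_tl_fold     R_u -> 0          gamma_R
#'   R_f -> 0          gamma_R       P  -> 0           gamma_P
#' }
#' The simulation is exact and bitwise reproducible: identical
#' \code{(params, init, t_end, seed, record)} give an identical event
#' sequence (R's Mersenne-Twister stream).
#'
#' @param params a [model_params()] object.
#' @param init named numeric vector of the initial state with elements
#'   \code{promoter} (0 = D0, 1 = D1), \code{R_u}, \code{R_f}, \code{P},
#'   and optionally \code{t} (start time, default 0).
#' @param t_end end time; must exceed the start time.
#' @param seed integer RNG seed; \code{NULL} continues the current stream.
#' @param record \code{"events"} (state after every reaction, plus the
#'   initial state) or \code{"grid"} (state sampled every \code{dt}).
#' @param dt grid spacing when \code{record = "grid"}.
#'
#' @return An object of class \code{"ssa_trajectory"}: a data.frame with
#'   columns \code{time}, \code{promoter}, \code{R_u}, \code{R_f}, \code{P},
#'   with the parameters and seed attached as attributes.
#' @examples
#' p <- model_params(k_on = 1, k_off = 1, v_tx = 20, gamma_R = 1)
#' tr <- simulate_ssa(p, t_end = 50, seed = 1)
#' tail(tr)
#' @export
simulate_ssa <- function(params, init = default_init(params),
                         t_end, seed = NULL,
                         record = c("events", "grid"), dt = 1) {
  stopifnot(inherits(params, "model_params"))
  record <- match.arg(record)
  init <- complete_init(init)
  t0 <- init[["t"]]
  if (!is.numeric(t_end) || t_end <= t0)
    stop("t_end must exceed the initial time", call. = FALSE)
  if (record == "grid" && (!is.numeric(dt) || dt <= 0))
    stop("dt must be > 0 for grid recording", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- ssa_run_cpp(cpp_rates(params),
                   c(init[["promoter"]], init[["R_u"]], init[["R_f"]],
                     init[["P"]]),
                   t0, t_end,
                   if (record == "events") 1L else 2L, dt)
  tr <- as.data.frame(m)
  attr(tr, "params") <- params
  attr(tr, "seed") <- seed
  attr(tr, "record") <- record
  class(tr) <- c("ssa_trajectory", "data.frame")
  tr
}

#' Default initial state for a simulation
#'
#' Empty cell (no mRNA, no protein) with the promoter active; for a
#' switching promoter the ensemble machinery randomises the initial
#' promoter state instead.
#'
#' @param params a [model_params()] object.
#' @return Named numeric vector \code{(promoter, R_u, R_f, P, t)}.
#' @export
default_init <- function(params) {
  c(promoter = 1, R_u = 0, R_f = 0, P = 0, t = 0)
}

complete_init <- function(init) {
  full <- c(promoter = 1, R_u = 0, R_f = 0, P = 0, t = 0)
  if (is.null(names(init)) && length(init) == length(full))
    names(init) <- names(full)
  full[names(init)] <- init
  counts <- full[c("R_u", "R_f", "P")]
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (!full[["promoter"]] %in% c(0, 1))
    stop("promoter must be 0 (D0) or 1 (D1)", call. = FALSE)
  full
}

# rate vector for the C++ core: transcription split between unfolded and
# folded nascent transcripts according to the birth-state model
cpp_rates <- function(params) {
  pu <- birth_unfolded_prob(params)
  c(params$k_on, params$k_off,
    params$v_tx * pu, params$v_tx * (1 - pu),
    params$k_fold, params$k_unfold,
    params$k_tl, params$k_tl_fold,
    params$gamma_R, params$gamma_P)
}

# deterministic per-cell substream: distinct for distinct cells at a fixed
# seed (2147483647 is prime), always a valid 32-bit integer
cell_seed <- function(seed, cell) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                as.numeric(cell) * 1000003) %% 2147483647)
}

#' Default burn-in time for stationary sampling
#'
#' Ten times the slowest relaxation timescale,
#' \code{10 * max(1/gamma_R, 1/gamma_P)}.
#'
#' @param params a [model_params()] object.
#' @return Burn-in time (same units as the rates).
#' @export
default_burn_in <- function(params) {
  10 * max(1 / params$gamma_R, 1 / params$gamma_P)
}

#' Stationary ensemble moments by stochastic simulation
#'
#' Simulates \code{n_cells} independent cells (per-cell RNG streams derived
#' from \code{(seed, cell index)}), samples each at \code{t_sample}, and
#' returns means, variances, CVs and Fano factors for total mRNA
#' (\code{R_u + R_f}), unfolded mRNA and protein. Each cell starts empty;
#' its initial promoter state is drawn from the promoter's stationary
#' distribution \code{k_on/(k_on+k_off)}. \code{t_sample} should be at
#' least \code{burn_in}; stationarity is the user's responsibility
#' (documented, not enforced beyond this check).
#'
#' @param params a [model_params()] object.
#' @param n_cells ensemble size (>= 2).
#' @param t_sample time at which each cell is sampled; default
#'   \code{burn_in}.
#' @param burn_in relaxation period; default [default_burn_in()].
#' @param seed integer seed for the ensemble.
#'
#' @return An object of class \code{"ensemble_moments"}: a data.frame with
#'   one row per species (\code{R_total}, \code{R_u}, \code{P}) and columns
#'   \code{mean}, \code{var}, \code{sd}, \code{cv}, \code{fano}; the raw
#'   per-cell samples are attached as attribute \code{"samples"}.
#' @examples
#' p <- model_params(k_on = 1, k_off = 1, v_tx = 20, gamma_R = 1)
#' ensemble_moments(p, n_cells = 200, seed = 1)
#' @export
ensemble_moments <- function(params, n_cells,
                             t_sample = NULL, burn_in = NULL, seed = 1) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(n_cells) || n_cells < 2)
    stop("n_cells must be >= 2", call. = FALSE)
  n_cells <- as.integer(n_cells)
  if (is.null(burn_in)) burn_in <- default_burn_in(params)
  if (is.null(t_sample)) t_sample <- burn_in
  if (t_sample < burn_in)
    stop("t_sample must be >= burn_in", call. = FALSE)

  rates <- cpp_rates(params)
  p_on <- if (params$k_on + params$k_off > 0)
    params$k_on / (params$k_on + params$k_off) else 1
  samples <- matrix(0, n_cells, 4,
                    dimnames = list(NULL, c("promoter", "R_u", "R_f", "P")))
  for (i in seq_len(n_cells)) {
    set.seed(cell_seed(seed, i))
    d0 <- as.numeric(runif(1) < p_on)
    m <- ssa_run_cpp(rates, c(d0, 0, 0, 0), 0, t_sample, 0L, 0)
    samples[i, ] <- m[nrow(m), 2:5]
  }
  species <- cbind(R_total = samples[, "R_u"] + samples[, "R_f"],
                   R_u = samples[, "R_u"],
                   P = samples[, "P"])
  out <- do.call(rbind, lapply(colnames(species), function(s) {
    x <- species[, s]
    m <- mean(x); v <- var(x)
    data.frame(species = s, mean = m, var = v, sd = sqrt(v),
               cv = if (m > 0) sqrt(v) / m else NA_real_,
               fano = if (m > 0) v / m else NA_real_)
  }))
  rownames(out) <- out$species
  attr(out, "samples") <- species
  attr(out, "n_cells") <- n_cells
  attr(out, "t_sample") <- t_sample
  attr(out, "params") <- params
  class(out) <- c("ensemble_moments", "data.frame")
  out
}

#' Protein-noise sweep over mRNA folding/unfolding kinetics
#'
#' Evaluates stationary ensemble moments over the Cartesian grid of folding
#' and unfolding rates, holding all other parameters fixed. Because folded
#' and unfolded mRNA degrade at the same rate, the stationary total-mRNA
#' mean is invariant across the grid; protein noise is not, which is the
#' point: slow interconversion partitions mRNA lifetimes into translatable
#' and silent episodes and inflates protein noise relative to fast
#' interconversion at the same unfolded fraction.
#'
#' @param base a [model_params()] object supplying all non-folding rates.
#' @param k_fold_grid,k_unfold_grid non-empty numeric vectors of rates; the
#'   sweep covers their Cartesian product.
#' @param n_cells ensemble size per grid point (>= 2).
#' @param t_sample,burn_in as in [ensemble_moments()].
#' @param seed integer seed; each grid point gets a derived subseed.
#'
#' @return data.frame with one row per grid point: \code{k_fold},
#'   \code{k_unfold}, \code{mean_P}, \code{cv_P}, \code{mean_R_total},
#'   \code{cv_R_total}.
#' @export
folding_noise_sweep <- function(base, k_fold_grid, k_unfold_grid,
                                n_cells, t_sample = NULL, burn_in = NULL,
                                seed = 1) {
  stopifnot(inherits(base, "model_params"))
  if (length(k_fold_grid) == 0 || length(k_unfold_grid) == 0)
    stop("rate grids must be non-empty", call. = FALSE)
  if (n_cells < 2) stop("n_cells must be >= 2", call. = FALSE)
  grid <- expand.grid(k_fold = k_fold_grid, k_unfold = k_unfold_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base
    p$k_fold <- grid$k_fold[i]
    p$k_unfold <- grid$k_unfold[i]
    em <- ensemble_moments(p, n_cells, t_sample, burn_in,
                           seed = cell_seed(seed, i))
    data.frame(k_fold = p$k_fold, k_unfold = p$k_unfold,
               mean_P = em["P", "mean"], cv_P = em["P", "cv"],
               mean_R_total = em["R_total", "mean"],
               cv_R_total = em["R_total", "cv"])
  })
  do.call(rbind, rows)
}
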