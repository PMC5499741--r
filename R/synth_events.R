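#' Specification of a synthetic flow-cytometry population
#'
#' Describes a cytometry acquisition to be emulated: a dense core of intact
#' cells in the FSC-SSC plane, one or two fluorescence channels whose
#' per-event intensities combine a shared multiplicative extrinsic factor
#' and channel-specific intrinsic factors (both lognormal), an optional
#' additive autofluorescence background, and a debris fraction placed below
#' the forward-scatter threshold so that the documented scatter gates can
#' remove it.
#'
#' The lognormal intrinsic factors are calibrated so that the population
#' functionals measured by the dual-reporter estimators equal the requested
#' values exactly: the intrinsic log-variance is
#' \code{log(1 + eta_int^2/(1 + eta_ext^2))}, which makes the true
#' per-channel total CV equal \code{sqrt(eta_int^2 + eta_ext^2)} and the
#' dual-reporter intrinsic and extrinsic squared-noise functionals equal
#' \code{eta_int^2} and \code{eta_ext^2} with no second-order bias.
#'
#' @param n_events total number of events (core + debris), >= 1.
#' @param channels named numeric vector of expected in-core channel
#'   intensities (channel units), e.g. \code{c(GFP = 1560)} or
#'   \code{c(GFP = 1560, RFP = 1490)}.
#' @param scatter_center length-2 vector, core centre \code{(FSC, SSC)}.
#' @param scatter_sd length-2 vector of core spreads.
#' @param eta_int per-channel intrinsic noise (fraction, CV scale).
#' @param eta_ext shared extrinsic noise (fraction).
#' @param autofluor_mean additive background intensity per channel
#'   (recycled); 0 disables.
#' @param autofluor_cv CV of the lognormal background.
#' @param debris_fraction fraction of events drawn as sub-threshold debris
#'   (FSC below 40 000) with 3x intensity CV; in [0, 1).
#' @param ext_scatter_coupling optional coupling (log-intensity units per
#'   standardised scatter deviation) between the extrinsic factor and the
#'   cell's position in the FSC-SSC plane; positive values make gated CV and
#'   extrinsic noise grow with gate radius. Default 0.
#' @param acquisition_seconds acquisition window; event TIME is uniform
#'   over it (the first second is meant to be trimmed downstream).
#' @param seed integer seed.
#' @return An object of class \code{"population_spec"} (named list).
#' @examples
#' spec <- population_spec(n_events = 1000, channels = c(GFP = 1560),
#'                         eta_int = 0.118, seed = 1)
#' ev <- gen_population_events(spec)
#' head(ev)
#' @export
population_spec <- function(n_events,
                            channels,
                            scatter_center = c(59000, 27000),
                            scatter_sd = c(6000, 6000),
                            eta_int = 0.1,
                            eta_ext = 0,
                            autofluor_mean = 0,
                            autofluor_cv = 0.25,
                            debris_fraction = 0,
                            ext_scatter_coupling = 0,
                            acquisition_seconds = 10,
                            seed = 1) {
  if (!is.numeric(n_events) || n_events < 1)
    stop("n_events must be >= 1", call. = FALSE)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named vector of intensities", call. = FALSE)
  if (any(channels < 0) || any(autofluor_mean < 0))
    stop("intensities must be >= 0", call. = FALSE)
  if (eta_int < 0 || eta_int > 1 || eta_ext < 0 || eta_ext > 1 ||
      debris_fraction < 0 || debris_fraction >= 1)
    stop("noise fractions must lie in [0, 1] and debris_fraction in [0, 1)",
         call. = FALSE)
  structure(list(n_events = as.integer(n_events), channels = channels,
                 scatter_center = scatter_center, scatter_sd = scatter_sd,
                 eta_int = eta_int, eta_ext = eta_ext,
                 autofluor_mean = autofluor_mean, autofluor_cv = autofluor_cv,
                 debris_fraction = debris_fraction,
                 ext_scatter_coupling = ext_scatter_coupling,
                 acquisition_seconds = acquisition_seconds,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# lognormal with exact mean 1 and CV `cv` (degenerate at cv = 0)
rlnorm_cv1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic cytometry event table
#'
#' Draws a population per a [population_spec()]: core events with normal
#' FSC/SSC around the scatter centre; per event one shared lognormal
#' extrinsic factor applied multiplicatively to every fluorescence channel
#' and independent per-channel lognormal intrinsic factors; optional
#' additive lognormal autofluorescence; debris events below the FSC
#' threshold with 3x intensity CV; TIME uniform over the acquisition
#' window. Events are ordered by TIME. The synthetic provenance of each
#' event is retained in attribute \code{"provenance"} (\code{"core"} /
#' \code{"debris"}) for test assertions only; it is not written to files.
#'
#' @param spec a [population_spec()].
#' @return An event table: data.frame with columns \code{TIME}, \code{FSC},
#'   \code{SSC} and one column per fluorescence channel.
#' @export
gen_population_events <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_events
  n_debris <- round(n * spec$debris_fraction)
  n_core <- n - n_debris
  ch_names <- names(spec$channels)
  k <- length(ch_names)

  # --- core events ---------------------------------------------------------
  z1 <- rnorm(n_core); z2 <- rnorm(n_core)
  fsc <- pmax(spec$scatter_center[1] + spec$scatter_sd[1] * z1, 0)
  ssc <- pmax(spec$scatter_center[2] + spec$scatter_sd[2] * z2, 0)
  log_ext <- if (spec$eta_ext > 0) {
    s2 <- log(1 + spec$eta_ext^2)
    rnorm(n_core, -s2 / 2, sqrt(s2))
  } else rep(0, n_core)
  if (spec$ext_scatter_coupling != 0)
    log_ext <- log_ext + spec$ext_scatter_coupling * (z1 + z2) / sqrt(2)
  ext <- exp(log_ext)
  eta_int_eff <- spec$eta_int / sqrt(1 + spec$eta_ext^2)
  af_mean <- rep_len(spec$autofluor_mean, k)
  core <- sapply(seq_len(k), function(j) {
    x <- spec$channels[j] * ext * rlnorm_cv1(n_core, eta_int_eff)
    if (af_mean[j] > 0)
      x <- x + af_mean[j] * rlnorm_cv1(n_core, spec$autofluor_cv)
    x
  })
  core <- matrix(core, nrow = n_core, dimnames = list(NULL, ch_names))

  # --- debris events (below the documented FSC threshold) ------------------
  if (n_debris > 0) {
    dfsc <- runif(n_debris, 1000, 39000)
    dssc <- runif(n_debris, 1000, 89000)
    dmat <- sapply(seq_len(k), function(j)
      spec$channels[j] * rlnorm_cv1(n_debris,
                                    min(3 * sqrt(spec$eta_int^2 +
                                                   spec$eta_ext^2), 3)))
    dmat <- matrix(dmat, nrow = n_debris, dimnames = list(NULL, ch_names))
    fsc <- c(fsc, dfsc); ssc <- c(ssc, dssc)
    core <- rbind(core, dmat)
  }

  prov <- c(rep("core", n_core), rep("debris", n_debris))
  tim <- runif(n, 0, spec$acquisition_seconds)
  ord <- order(tim)
  ev <- data.frame(TIME = tim[ord], FSC = fsc[ord], SSC = ssc[ord],
                   core[ord, , drop = FALSE])
  names(ev) <- c("TIME", "FSC", "SSC", ch_names)
  attr(ev, "provenance") <- prov[ord]
  attr(ev, "spec") <- spec
  ev
}

#' Generate a dual-reporter cytometry event table
#'
#' As [gen_population_events()] but requires exactly two fluorescence
#' channels (e.g. yEGFP and mRuby3 driven by identical promoters). By the
#' generator's calibration, the population's true dual-reporter noise
#' functionals equal \code{eta_int^2} and \code{eta_ext^2} exactly.
#'
#' @param spec a [population_spec()] with exactly two channels.
#' @return Event table with columns \code{TIME}, \code{FSC}, \code{SSC}
#'   and the two channels.
#' @examples
#' spec <- population_spec(n_events = 5000,
#'                         channels = c(GFP = 1560, RFP = 1490),
#'                         eta_int = 0.1, eta_ext = 0.1, seed = 1)
#' ev <- gen_dual_reporter_events(spec)
#' @export
gen_dual_reporter_events <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (length(spec$channels) != 2)
    stop("dual-reporter population requires exactly two channels",
         call. = FALSE)
  gen_population_events(spec)
}

#' Write an event table to TSV or FCS3.0
#'
#' TSV uses the dialect \code{TIME<TAB>FSC<TAB>SSC<TAB><CH1>[<TAB><CH2>]},
#' one event per row, and round-trips losslessly through [read_events()].
#' FCS3.0 writes a single dataset with 32-bit float parameters annotated
#' with an 18-bit range (\code{$PnR} = 262144), matching a cytometer export
#' at 2^18 resolution; values at or above 2^18 raise a range error unless
#' \code{clip = TRUE}.
#'
#' @param events event table (data.frame with TIME/FSC/SSC/channels, TIME
#'   optional).
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"fcs3"}.
#' @param clip clip out-of-range values to 2^18 - 1 instead of erroring
#'   (FCS only).
#' @return \code{path}, invisibly.
#' @export
write_events <- function(events, path, format = c("tsv", "fcs3"),
                         clip = FALSE) {
  format <- match.arg(format)
  stopifnot(is.data.frame(events))
  if (format == "tsv") {
    write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_fcs3(events, path, clip = clip)
  }
  invisible(path)
}
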