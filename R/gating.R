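#' Read a cytometry event table from TSV or FCS3.0
#'
#' TSV must carry a header line with columns \code{FSC}, \code{SSC}, at
#' least one fluorescence channel, and optionally \code{TIME}. FCS3.0
#' parameter names are mapped to table columns via \code{channel_map}
#' (FCS parameter name -> table column name), so instrument names such as
#' \code{"FSC-A"} can be mapped to \code{"FSC"}. Tables lacking a TIME
#' parameter load with TIME absent; [trim_time()] then degrades to a no-op
#' with a warning.
#'
#' @param path input file.
#' @param format \code{"tsv"}, \code{"fcs3"}, or \code{"auto"} (by file
#'   extension: \code{.fcs} reads as FCS3.0).
#' @param channel_map optional named character vector renaming columns on
#'   load, e.g. \code{c("FSC-A" = "FSC", "SSC-A" = "SSC")}.
#' @return Event table (data.frame) with \code{FSC}, \code{SSC}, optional
#'   \code{TIME}, and one column per fluorescence channel.
#' @export
read_events <- function(path, format = c("auto", "tsv", "fcs3"),
                        channel_map = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs3" else "tsv"
  ev <- switch(format,
               tsv = read.delim(path, check.names = FALSE),
               fcs3 = read_fcs3(path))
  if (!is.null(channel_map)) {
    hit <- names(ev) %in% names(channel_map)
    names(ev)[hit] <- channel_map[names(ev)[hit]]
  }
  for (req in c("FSC", "SSC"))
    if (!req %in% names(ev))
      stop("required channel '", req, "' is absent from ", path,
           call. = FALSE)
  if (!any(!names(ev) %in% c("TIME", "FSC", "SSC")))
    stop("no fluorescence channel found in ", path, call. = FALSE)
  ev
}

# fluorescence columns of an event table
fluor_channels <- function(events) {
  setdiff(names(events), c("TIME", "FSC", "SSC"))
}

#' Trim unstable flow at the start and end of an acquisition
#'
#' Removes events recorded during the first \code{head} seconds and the
#' final \code{tail} seconds of the acquisition, where sample flow through
#' the cytometer is unstable.
#'
#' @param events event table.
#' @param head seconds removed from the start (default 1.0).
#' @param tail seconds removed from the end (default 0.2).
#' @return The trimmed event table. If TIME is absent the input is
#'   returned unchanged with a warning.
#' @export
trim_time <- function(events, head = 1.0, tail = 0.2) {
  if (!"TIME" %in% names(events)) {
    warning("TIME channel absent; time trimming skipped", call. = FALSE)
    return(events)
  }
  span <- max(events$TIME) - min(events$TIME)
  if (head + tail >= span)
    stop("head + tail trim (", head + tail,
         " s) covers the whole acquisition span (", signif(span, 4), " s)",
         call. = FALSE)
  keep <- events$TIME >= min(events$TIME) + head &
    events$TIME <= max(events$TIME) - tail
  subset_events(events, keep)
}

#' Scatter threshold gate against debris and aggregates
#'
#' Retains events whose forward and side scatter fall inside closed
#' intervals; the defaults are the thresholds used to exclude cellular
#' debris (low scatter) and aggregated cells (high scatter).
#'
#' @param events event table.
#' @param fsc_range,ssc_range closed \code{[lo, hi]} intervals.
#' @return The gated event table (possibly empty, with a warning).
#' @export
scatter_threshold_gate <- function(events, fsc_range = c(40000, 100000),
                                   ssc_range = c(10000, 90000)) {
  keep <- events$FSC >= fsc_range[1] & events$FSC <= fsc_range[2] &
    events$SSC >= ssc_range[1] & events$SSC <= ssc_range[2]
  if (!any(keep)) warning("scatter gate retained no events", call. = FALSE)
  subset_events(events, keep)
}

subset_events <- function(events, keep) {
  prov <- attr(events, "provenance")
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(prov)) attr(out, "provenance") <- prov[keep]
  out
}

#' Highest-density centre of the FSC-SSC scatterplot
#'
#' Bins the FSC-SSC plane into square bins of \code{bin_width} and returns
#' the centre of the maximal-count bin; ties are broken by the smallest
#' (FSC, SSC) pair lexicographically. A manual centre, when supplied,
#' overrides the histogram estimate and is returned verbatim.
#'
#' @param events event table with at least 100 events (documented minimum
#'   for a stable mode).
#' @param bin_width histogram bin width in channel units (default 1000).
#' @param manual optional length-2 numeric \code{(FSC, SSC)} override.
#' @return Named numeric vector \code{c(FSC = ..., SSC = ...)}.
#' @export
density_center <- function(events, bin_width = 1000, manual = NULL) {
  if (!is.null(manual)) {
    stopifnot(length(manual) == 2)
    return(c(FSC = manual[1], SSC = manual[2]))
  }
  if (nrow(events) < 100)
    stop("density_center needs >= 100 events for a stable mode",
         call. = FALSE)
  ix <- floor(events$FSC / bin_width)
  iy <- floor(events$SSC / bin_width)
  tab <- table(ix, iy)
  mx <- max(tab)
  hits <- which(tab == mx, arr.ind = TRUE)
  bx <- as.numeric(rownames(tab))[hits[, 1]]
  by <- as.numeric(colnames(tab))[hits[, 2]]
  ord <- order(bx, by)[1]   # lexicographic tie-break, smallest (FSC, SSC)
  c(FSC = (bx[ord] + 0.5) * bin_width, SSC = (by[ord] + 0.5) * bin_width)
}

#' Euclidean distance of each event from a scatter centre
#'
#' \deqn{d_i = \sqrt{(FSC_i - FSC_c)^2 + (SSC_i - SSC_c)^2}}
#'
#' @param events event table.
#' @param center length-2 numeric \code{(FSC, SSC)} centre.
#' @return Numeric vector of per-event distances.
#' @examples
#' radial_distance(data.frame(FSC = 62000, SSC = 31000), c(59000, 27000))
#' @export
radial_distance <- function(events, center) {
  sqrt((events$FSC - center[1])^2 + (events$SSC - center[2])^2)
}

#' Coefficient of variation, in percent
#'
#' \code{CV = s/m}: 100 times the sample standard deviation (n-1
#' denominator) over the mean.
#'
#' @param values numeric vector, length >= 2, positive mean.
#' @return CV in percent.
#' @examples
#' cv_stat(c(2, 4, 4, 4, 5, 5, 7, 9))
#' @export
cv_stat <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("CV is undefined for mean <= 0", call. = FALSE)
  100 * sd(values) / m
}

#' Radial gate around a scatter centre
#'
#' Selects events within \code{radius} of \code{center} in the FSC-SSC
#' plane and computes each fluorescence channel's gated mean and CV.
#'
#' @param events event table.
#' @param center length-2 \code{(FSC, SSC)} centre.
#' @param radius gate radius in channel units (> 0); default 4000, the
#'   compromise at which run-to-run variation is minimal while the gated
#'   cell count stays statistically useful.
#' @return An object of class \code{"gate_result"}: a list with
#'   \code{center}, \code{radius}, \code{n_in}, \code{mean} (named per
#'   channel), \code{cv_percent} (named per channel), and the gated
#'   \code{events}.
#' @export
radial_gate <- function(events, center, radius = 4000) {
  if (!is.numeric(radius) || radius <= 0)
    stop("radius must be > 0", call. = FALSE)
  d <- radial_distance(events, center)
  inside <- d <= radius
  if (!any(inside))
    stop("empty gate: no events within radius ", radius, call. = FALSE)
  g <- subset_events(events, inside)
  chans <- fluor_channels(g)
  res <- list(center = c(FSC = unname(center[1]), SSC = unname(center[2])),
              radius = radius, n_in = nrow(g),
              mean = vapply(g[chans], mean, numeric(1)),
              cv_percent = vapply(g[chans], cv_stat, numeric(1)),
              events = g)
  class(res) <- "gate_result"
  res
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("radial gate: r = %g around (FSC %g, SSC %g); %d events\n",
              x$radius, x$center[1], x$center[2], x$n_in))
  for (ch in names(x$mean))
    cat(sprintf("  %s: mean %.4g, CV %.3g%%\n", ch, x$mean[ch],
                x$cv_percent[ch]))
  invisible(x)
}

#' Gated CV as a function of gate radius
#'
#' Applies [radial_gate()] at each radius and tabulates the gated cell
#' count, mean and CV per channel. Radii whose gate is empty are reported
#' as missing rows (with a warning), not failures.
#'
#' @param events event table.
#' @param center length-2 \code{(FSC, SSC)} centre.
#' @param radii increasing positive radii.
#' @return data.frame with columns \code{radius}, \code{n_in}, and
#'   \code{mean_<ch>}, \code{cv_<ch>} per fluorescence channel.
#' @export
cv_vs_radius <- function(events, center, radii) {
  if (length(radii) == 0 || any(radii <= 0) || is.unsorted(radii,
                                                           strictly = TRUE))
    stop("radii must be non-empty, positive and strictly increasing",
         call. = FALSE)
  chans <- fluor_channels(events)
  rows <- lapply(radii, function(r) {
    g <- tryCatch(radial_gate(events, center, r), error = function(e) NULL)
    if (is.null(g)) {
      warning("empty gate at radius ", r, "; point skipped", call. = FALSE)
      return(NULL)
    }
    row <- data.frame(radius = r, n_in = g$n_in)
    for (ch in chans) {
      row[[paste0("mean_", ch)]] <- g$mean[[ch]]
      row[[paste0("cv_", ch)]] <- g$cv_percent[[ch]]
    }
    row
  })
  do.call(rbind, rows)
}

#' The full gated-CV preprocessing pipeline
#'
#' Runs the four preprocessing steps in their fixed order — time trim,
#' scatter threshold gate, density-centre estimate, radial gate — and
#' returns the final [radial_gate()] result.
#'
#' @param events event table.
#' @param radius gate radius (default 4000).
#' @param center \code{"auto"} (density centre) or a length-2 numeric
#'   manual centre.
#' @param trim_head,trim_tail seconds trimmed from the acquisition.
#' @param fsc_range,ssc_range scatter thresholds.
#' @param bin_width density-histogram bin width.
#' @return A \code{"gate_result"}, with the estimated centre attached.
#' @export
gate_pipeline <- function(events, radius = 4000, center = "auto",
                          trim_head = 1.0, trim_tail = 0.2,
                          fsc_range = c(40000, 100000),
                          ssc_range = c(10000, 90000),
                          bin_width = 1000) {
  ev <- trim_time(events, trim_head, trim_tail)
  ev <- scatter_threshold_gate(ev, fsc_range, ssc_range)
  ctr <- if (identical(center, "auto"))
    density_center(ev, bin_width) else c(FSC = center[1], SSC = center[2])
  radial_gate(ev, ctr, radius)
}
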