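## Flow-cytometry layer: FMO-derived gate thresholds, Boolean isotype
## combination counting on DAPI+ non-bead events, and counting-bead
## calibrated absolute loads.
##
## Event tables are plain data.frames with one row per event: a `dapi`
## column, one column per stained isotype channel (e.g. `iga`, `igm`,
## `igg`, or `igg1`..`igg4`), and a logical `is_bead` column. Intensities
## are arbitrary fluorescence units, >= 0. The same machinery serves the
## three-channel IgA/IgM/IgG panel and the four-channel IgG1-4 subtype
## panel; panels are never joined at event level (they are separate
## stains).

ig_channel_names <- function(events) {
  setdiff(names(events), c("event_id", "dapi", "is_bead"))
}

#' Derive gate thresholds from FMO control events
#'
#' The positivity threshold for each channel is the nearest-rank empirical
#' quantile of that channel's intensities in the fluorescence-minus-one
#' (FMO) control acquisition. The default 0.999 quantile places the gate
#' just above essentially all unstained signal.
#'
#' @param fmo_events event `data.frame` (see module header); beads, if
#'   present, are excluded.
#' @param quantile quantile in `(0, 1]` of the FMO intensity distribution
#'   (nearest-rank rule; 0 is accepted and returns the minimum).
#' @param channels channels to gate; default every isotype channel in
#'   `fmo_events`.
#' @return A named numeric vector of class `gate_thresholds` with
#'   attribute `quantile` recording the FMO quantile used.
#' @export
derive_thresholds <- function(fmo_events, quantile = 0.999,
                              channels = NULL) {
  stopifnot(is.data.frame(fmo_events), quantile >= 0, quantile <= 1)
  if (!is.null(fmo_events$is_bead))
    fmo_events <- fmo_events[!fmo_events$is_bead, , drop = FALSE]
  channels <- channels %||% ig_channel_names(fmo_events)
  if (!length(channels)) stop("no isotype channels found in FMO events")
  thr <- vapply(channels, function(ch) {
    x <- fmo_events[[ch]]
    if (is.null(x) || !length(x))
      stop("FMO events empty for channel '", ch, "'")
    nearest_rank_quantile(x, quantile)
  }, numeric(1))
  structure(thr, quantile = quantile, class = "gate_thresholds")
}

#' Count events per Boolean isotype combination
#'
#' Gates on DAPI+ non-bead events (DAPI positivity uses `thresholds["dapi"]`
#' when supplied, otherwise every non-bead event counts as DAPI+), then
#' partitions them into the 2^k Boolean combinations of the k stained
#' channels. Positivity is strict (`intensity > threshold`), so events tied
#' with the gate are negative — the conservative FMO convention.
#'
#' @param events event `data.frame`.
#' @param thresholds named thresholds from [derive_thresholds()]; must
#'   cover every stained channel in `events`.
#' @return An `ig_profile`: list with `counts` (named integer vector over
#'   the 2^k combinations; names like `"iga+igg"`, all-negative is
#'   `"none"`), `combo` (logical matrix 2^k x k), `channels`, `n_gated`
#'   (DAPI+ non-bead total) and `n_beads`.
#' @export
classify_events <- function(events, thresholds) {
  stopifnot(is.data.frame(events))
  channels <- ig_channel_names(events)
  missing_thr <- setdiff(channels, names(thresholds))
  if (length(missing_thr))
    stop("thresholds missing for channel(s): ",
         paste(missing_thr, collapse = ", "))
  is_bead <- if (is.null(events$is_bead)) rep(FALSE, nrow(events)) else
    as.logical(events$is_bead)
  gated <- !is_bead
  if ("dapi" %in% names(thresholds) && !is.null(events$dapi))
    gated <- gated & events$dapi > thresholds[["dapi"]]
  k <- length(channels)
  combo <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  colnames(combo) <- channels
  labels <- apply(combo, 1, function(b)
    if (!any(b)) "none" else paste(channels[b], collapse = "+"))
  pos <- vapply(channels, function(ch)
    events[[ch]][gated] > thresholds[[ch]], logical(sum(gated)))
  if (sum(gated) == 1L) pos <- matrix(pos, nrow = 1,
                                      dimnames = list(NULL, channels))
  idx <- if (sum(gated) == 0L) integer(0) else
    as.integer(pos %*% 2^(seq_len(k) - 1)) + 1L
  counts <- tabulate(idx, nbins = 2^k)
  names(counts) <- labels
  structure(list(counts = counts, combo = combo, channels = channels,
                 n_gated = sum(gated), n_beads = sum(is_bead)),
            class = "ig_profile")
}

#' @export
print.ig_profile <- function(x, ...) {
  cat(sprintf("ig_profile: %d gated events, %d beads, channels: %s\n",
              x$n_gated, x$n_beads, paste(x$channels, collapse = ", ")))
  print(x$counts)
  invisible(x)
}

#' Marginal positive-event count for one isotype
#'
#' @param profile an `ig_profile`.
#' @param channel channel name (e.g. `"iga"`).
#' @param mode `"any"` counts every combination containing the isotype
#'   (single + multi coated); `"single"` counts only the combination where
#'   it is the sole positive channel.
#' @return integer event count.
#' @export
marginal_count <- function(profile, channel, mode = c("any", "single")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "ig_profile"),
            channel %in% profile$channels)
  b <- profile$combo[, channel]
  keep <- if (mode == "any") b else b & rowSums(profile$combo) == 1
  sum(profile$counts[keep])
}

#' Absolute bacterial load from counting-bead calibration
#'
#' `load = (cell_events / bead_events) * beads_added * dilution_factor /
#' sample_mass`. Every component is retained in the result for audit.
#'
#' @param cell_events gated bacterial events (DAPI+ non-bead).
#' @param bead_events counting-bead events observed (must be >= 1).
#' @param beads_added number of beads spiked into the tube.
#' @param dilution_factor fold-dilution of the homogenate before
#'   acquisition (dimensionless; the worked default in examples is 150).
#' @param sample_mass grams of feces the tube represents.
#' @return A list of class `absolute_load` with `load` (bacteria per gram)
#'   and all calibration components.
#' @export
absolute_load <- function(cell_events, bead_events, beads_added,
                          dilution_factor, sample_mass) {
  check_nonneg(cell_events, "cell_events")
  if (!is.numeric(bead_events) || bead_events < 1)
    stop("calibration error: bead_events must be >= 1 (no beads observed)")
  check_positive(beads_added, "beads_added")
  check_positive(dilution_factor, "dilution_factor")
  check_positive(sample_mass, "sample_mass")
  load <- (cell_events / bead_events) * beads_added * dilution_factor /
    sample_mass
  structure(list(load = load, cell_events = cell_events,
                 bead_events = bead_events, beads_added = beads_added,
                 dilution_factor = dilution_factor,
                 sample_mass = sample_mass),
            class = "absolute_load")
}

#' @export
print.absolute_load <- function(x, ...) {
  cat(sprintf(
    "absolute_load: %.3g bacteria/g (%d cells / %d beads, %g beads added, %gx dilution, %g g)\n",
    x$load, x$cell_events, x$bead_events, x$beads_added,
    x$dilution_factor, x$sample_mass))
  invisible(x)
}

#' Distribute a total load over the isotype combinations
#'
#' Each Boolean combination (including all-negative) receives
#' `total_load * count / n_gated`, so the combination loads always sum to
#' the total load exactly.
#'
#' @param profile an `ig_profile`.
#' @param total_load total bacteria/g, either a number or an
#'   [absolute_load()] object.
#' @return named numeric vector of bacteria/g per combination.
#' @export
combo_loads <- function(profile, total_load) {
  stopifnot(inherits(profile, "ig_profile"))
  if (inherits(total_load, "absolute_load")) total_load <- total_load$load
  if (profile$n_gated == 0L)
    stop("no DAPI+ non-bead events; combination loads undefined")
  total_load * profile$counts / profile$n_gated
}

#' Coated load for one isotype marginal
#'
#' Convenience wrapper: `total_load * marginal_count / n_gated`, matching
#' the "any IgA" / "any IgM" sort gates.
#'
#' @inheritParams combo_loads
#' @inheritParams marginal_count
#' @return bacteria/g carried by events positive for `channel`.
#' @export
coated_load <- function(profile, total_load, channel,
                        mode = c("any", "single")) {
  if (inherits(total_load, "absolute_load")) total_load <- total_load$load
  if (profile$n_gated == 0L) stop("no gated events")
  total_load * marginal_count(profile, channel, match.arg(mode)) /
    profile$n_gated
}

#' Fraction of gated events positive for each channel
#'
#' @param profile an `ig_profile`.
#' @return named numeric vector of per-channel coating fractions (relative
#'   to DAPI+ non-bead events).
#' @export
coating_fractions <- function(profile) {
  stopifnot(inherits(profile, "ig_profile"))
  if (profile$n_gated == 0L) stop("no gated events")
  vapply(profile$channels,
         function(ch) marginal_count(profile, ch, "any") / profile$n_gated,
         numeric(1))
}
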