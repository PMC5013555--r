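# Observation models.
#
# Classical local sampling (kicknet): every aquatic species present at a site
# is detected independently with probability delta_classical, so the
# expected measured alpha-diversity is delta_classical * alpha_real(x).
#
# eDNA sampling: the signal available at site x integrates presence over the
# whole upstream network. Transport (net of shedding and degradation) is
# instantiated as a first-order exponential decay in along-stream distance
# with scale lambda, and detection of a species from signal c follows a
# Poisson-count model, p = 1 - exp(-delta_edna * c): very few molecules
# suffice, and detection saturates. This is one admissible instantiation of
# the catchment-integration model; its expectation is available in closed
# form and is cross-checked against the simulation in the test suite.

#' Observation-model parameters
#'
#' @param delta_classical per-species local detection probability of the
#'   classical (kicknet) method, in \[0, 1\]
#' @param delta_edna eDNA detection intensity per unit signal (>= 0).
#'   eDNA detection is highly sensitive -- very few molecules suffice -- so
#'   the default is high (10: a full local signal is detected with
#'   probability 0.99995, and even a signal diluted to 7 % of a unit source
#'   is detected every other time). Use
#'   `matched_delta_edna(delta_classical)` to instead match the classical
#'   method's per-unit-signal detection probability.
#' @param transport_scale eDNA transport scale lambda, km (> 0): e-folding
#'   distance of the downstream signal decay. Empirical transport distances
#'   span roughly 0.24-12 km; default 3 km.
#' @param shedding_aquatic,shedding_terrestrial per-habitat shedding weights
#'   (>= 0) multiplying the transported signal; terrestrial material reaches
#'   the channel indirectly, hence the smaller default
#' @return an object of class `sampling_params`
#' @export
sampling_params <- function(delta_classical = 0.5,
                            delta_edna = 10,
                            transport_scale = 3,
                            shedding_aquatic = 1,
                            shedding_terrestrial = 0.2) {
  stopifnot(delta_classical >= 0, delta_classical <= 1,
            delta_edna >= 0, is.finite(delta_edna),
            transport_scale > 0, is.finite(transport_scale),
            shedding_aquatic >= 0, shedding_terrestrial >= 0)
  structure(list(delta_classical = delta_classical, delta_edna = delta_edna,
                 transport_scale = transport_scale,
                 shedding_aquatic = shedding_aquatic,
                 shedding_terrestrial = shedding_terrestrial),
            class = "sampling_params")
}

#' eDNA intensity matching the classical per-unit-signal detection rate
#'
#' Returns the intensity at which a species whose entire signal is local
#' (c = 1) is detected by the eDNA model with exactly `delta_classical`:
#' `-log(1 - delta_classical)`. At this matched intensity, upstream
#' integration can only add detections, so expected eDNA richness dominates
#' expected kicknet richness at every site.
#'
#' @param delta_classical classical detection probability in \[0, 1)
#' @return detection intensity
#' @export
matched_delta_edna <- function(delta_classical) {
  stopifnot(delta_classical >= 0, delta_classical < 1)
  -log(1 - delta_classical)
}

#' Classical (kicknet) sampling of a true community
#'
#' @param truth a truth-provenance `community_matrix`
#' @param delta_classical detection probability in \[0, 1\]
#' @param seed integer seed
#' @return a `community_matrix` with provenance `"kicknet"`: each locally
#'   present aquatic species is detected independently with probability
#'   `delta_classical`; terrestrial species are never detected
#' @export
sample_kicknet <- function(truth, delta_classical = 0.5, seed = 1L) {
  stopifnot(inherits(truth, "community_matrix"),
            attr(truth, "provenance") == "truth")
  if (delta_classical < 0 || delta_classical > 1)
    stop("delta_classical must be in [0, 1]", call. = FALSE)
  set.seed(split_seed(seed, 0L, stream = 3L))
  keep <- matrix(stats::runif(length(truth)) < delta_classical,
                 nrow = nrow(truth))
  out <- unclass(truth) * keep
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(truth)
  community_matrix(out, "kicknet")
}

#' Per-species eDNA signal available at a site
#'
#' Sums, over every reach u upstream of (and including) x, the species'
#' presence at u weighted by its habitat shedding weight and by the transport
#' kernel `exp(-d(u, x) / lambda)`. Barrier reaches truncate the sum. For
#' terrestrial species, "presence" means attachment of the species'
#' subcatchment to u.
#'
#' @param net a `river_network`
#' @param truth a truth `community_matrix` over the network's reaches
#' @param params a [sampling_params()] object
#' @param x reach id of the sampling site
#' @return named non-negative numeric vector, one entry per pool species
#' @export
edna_signal <- function(net, truth, params, x) {
  stopifnot(inherits(params, "sampling_params"))
  check_reach(net, x)
  up <- upstream_reaches(net, x)
  d <- vapply(up, function(u) along_stream_distance(net, u, x), numeric(1))
  kern <- exp(-d / params$transport_scale)

  pres <- unclass(truth)[up, , drop = FALSE]
  attachment <- attr(truth, "attachment")
  for (tx in names(attachment)) {
    if (attachment[[tx]] %in% up) pres[attachment[[tx]], tx] <- 1L
  }
  habitat <- ifelse(colnames(truth) %in% names(attachment),
                    params$shedding_terrestrial, params$shedding_aquatic)
  sig <- as.numeric(kern %*% pres) * habitat
  stats::setNames(sig, colnames(truth))
}

#' Draw an eDNA detection vector from a signal
#'
#' Each species is detected independently with probability
#' `1 - exp(-delta_edna * c)`.
#'
#' @param signal non-negative named numeric vector from [edna_signal()]
#' @param delta_edna detection intensity (>= 0)
#' @param seed integer seed
#' @return named 0/1 integer vector
#' @export
sample_edna <- function(signal, delta_edna, seed = 1L) {
  if (delta_edna < 0) stop("delta_edna must be >= 0", call. = FALSE)
  stopifnot(all(signal >= 0), all(is.finite(signal)))
  p <- 1 - exp(-delta_edna * signal)
  set.seed(split_seed(seed, 0L, stream = 4L))
  stats::setNames(as.integer(stats::runif(length(signal)) < p), names(signal))
}

#' eDNA detection matrix over a set of sites
#'
#' @inheritParams edna_signal
#' @param sites reach ids to sample
#' @param seed integer master seed (per-site seeds derived by splitting)
#' @return a `community_matrix` with provenance `"edna"`
#' @export
sample_edna_matrix <- function(net, truth, params, sites, seed = 1L) {
  rows <- lapply(seq_along(sites), function(i) {
    sig <- edna_signal(net, truth, params, sites[i])
    sample_edna(sig, params$delta_edna, seed = split_seed(seed, i, stream = 5L))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- sites
  community_matrix(m, "edna")
}

#' Analytic expected eDNA richness at a site
#'
#' Closed-form expectation of the eDNA observation model:
#' `sum_s (1 - exp(-delta_edna * c_s(x)))`, with no randomness. Serves as the
#' oracle the stochastic sampler is checked against.
#'
#' @inheritParams edna_signal
#' @return expected richness, a real >= 0
#' @export
expected_edna_richness <- function(net, truth, params, x) {
  sig <- edna_signal(net, truth, params, x)
  sum(1 - exp(-params$delta_edna * sig))
}
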