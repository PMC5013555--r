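# Synthetic "true" communities on a river network.
#
# The generative model is deliberately minimal: each aquatic species is
# seeded on a uniformly drawn reach and occupies other reaches with a
# Bernoulli probability that decays exponentially with along-stream distance
# from the seed. The decay scale rho is the single knob controlling the
# beta-diversity distance decay that the Mantel analysis later detects; the
# baseline occupancy controls mean local richness (alpha). Terrestrial
# species never occupy reaches: they attach to the subcatchment of one reach
# and exist only as eDNA sources entering the network there.

#' Define a species pool
#'
#' @param n_aquatic number of aquatic species
#' @param n_terrestrial number of terrestrial species (eDNA-only sources)
#' @return data.frame with columns `taxon_id`, `habitat`
#'   (`"aquatic"`/`"terrestrial"`)
#' @export
species_pool <- function(n_aquatic = 200L, n_terrestrial = 50L) {
  stopifnot(n_aquatic + n_terrestrial >= 1, n_aquatic >= 0, n_terrestrial >= 0)
  data.frame(
    taxon_id = c(sprintf("aq%03d", seq_len(n_aquatic)),
                 sprintf("te%03d", seq_len(n_terrestrial)))[
                   seq_len(n_aquatic + n_terrestrial)],
    habitat = rep(c("aquatic", "terrestrial"), c(n_aquatic, n_terrestrial)),
    stringsAsFactors = FALSE)
}

#' Community-generation parameters
#'
#' @param occupancy_range spatial autocorrelation scale rho, km (> 0): the
#'   e-folding distance of the occupancy decay away from a species' seed reach
#' @param baseline_occupancy occupancy probability at the seed reach, in (0, 1]
#' @param order_beta optional named numeric vector of per-Strahler-order
#'   multipliers (>= 0) on occupancy probability; higher values than 1 are
#'   clipped after multiplication, with a warning. Streams of an order given
#'   a multiplier below 1 host sparser, hence more distinct, communities.
#' @return an object of class `community_params`
#' @export
community_params <- function(occupancy_range = 2, baseline_occupancy = 0.7,
                             order_beta = NULL) {
  stopifnot(occupancy_range > 0,
            baseline_occupancy > 0, baseline_occupancy <= 1)
  if (!is.null(order_beta)) {
    stopifnot(is.numeric(order_beta), all(order_beta >= 0),
              !is.null(names(order_beta)))
  }
  structure(list(occupancy_range = occupancy_range,
                 baseline_occupancy = baseline_occupancy,
                 order_beta = order_beta),
            class = "community_params")
}

order_multiplier <- function(params, orders) {
  if (is.null(params$order_beta)) return(rep(1, length(orders)))
  m <- params$order_beta[as.character(orders)]
  m[is.na(m)] <- 1
  unname(m)
}

#' Construct a site-by-taxon incidence matrix
#'
#' @param incidence 0/1 matrix, rows = sites, columns = taxa (dimnames set)
#' @param provenance one of `"truth"`, `"kicknet"`, `"edna"`
#' @param attachment named character vector mapping terrestrial taxa to the
#'   reach whose subcatchment they occupy (eDNA entry point); may be empty
#' @return an integer matrix of class `community_matrix` with attributes
#'   `provenance` and `attachment`
#' @export
community_matrix <- function(incidence, provenance = c("truth", "kicknet", "edna"),
                             attachment = character(0)) {
  provenance <- match.arg(provenance)
  m <- as.matrix(incidence)
  if (!all(m %in% c(0, 1)))
    stop("incidence entries must be 0/1", call. = FALSE)
  storage.mode(m) <- "integer"
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("incidence must carry site and taxon dimnames", call. = FALSE)
  structure(m, provenance = provenance, attachment = attachment,
            class = c("community_matrix", class(m)))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix [%s]: %d sites x %d taxa, %d incidences\n",
              attr(x, "provenance"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Simulate true species communities on a network
#'
#' @param net a `river_network`
#' @param pool a [species_pool()] data.frame
#' @param params a [community_params()] object
#' @param seed integer master seed; per-species seeds are derived by fixed
#'   splitting so enlarging the pool never perturbs earlier species
#' @return a `community_matrix` with provenance `"truth"` over all reaches of
#'   the network. Terrestrial taxa have all-zero rows (they are not sampleable
#'   in the water) and carry their eDNA entry reach in the `attachment`
#'   attribute.
#' @export
simulate_true_communities <- function(net, pool, params, seed = 1L) {
  stopifnot(inherits(net, "river_network"), inherits(params, "community_params"))
  if (nrow(pool) < 1) stop("empty species pool", call. = FALSE)
  sites <- net$reaches$reach_id
  if (length(sites) < 1) stop("empty network", call. = FALSE)
  D <- distance_matrix(net)
  mult <- order_multiplier(params, net$reaches$strahler_order)

  inc <- matrix(0L, nrow = length(sites), ncol = nrow(pool),
                dimnames = list(sites, pool$taxon_id))
  attachment <- character(0)
  clipped <- FALSE
  for (s in seq_len(nrow(pool))) {
    set.seed(split_seed(seed, s, stream = 2L))
    k <- sample.int(length(sites), 1L)
    if (pool$habitat[s] == "terrestrial") {
      attachment[pool$taxon_id[s]] <- sites[k]
      next
    }
    p <- params$baseline_occupancy * mult *
      exp(-D[k, ] / params$occupancy_range)
    if (any(p > 1)) { clipped <- TRUE; p <- pmin(p, 1) }
    inc[, s] <- as.integer(stats::runif(length(sites)) < p)
  }
  if (clipped)
    warning("occupancy probabilities above 1 were clipped to 1", call. = FALSE)
  community_matrix(inc, "truth", attachment = attachment)
}

#' Pairwise distance and Jaccard dissimilarity of a truth matrix
#'
#' @param truth a `community_matrix`
#' @param net the `river_network` whose reaches name the matrix rows
#' @param sites optional subset of sites (default: all rows)
#' @return data.frame with one row per unordered site pair: `site_a`,
#'   `site_b`, `distance_km`, `jaccard` (dissimilarity in \[0, 1\], `NA` when
#'   both communities are empty)
#' @export
realized_beta <- function(truth, net, sites = rownames(truth)) {
  check_reach(net, sites)
  m <- truth[sites, , drop = FALSE]
  J <- jaccard_matrix(m)
  D <- distance_matrix(net, sites)
  pairs <- which(upper.tri(J), arr.ind = TRUE)
  data.frame(site_a = sites[pairs[, 1]], site_b = sites[pairs[, 2]],
             distance_km = D[pairs], jaccard = J[pairs],
             stringsAsFactors = FALSE)
}

#' Read / write incidence matrices as CSV
#'
#' First column `site_id`, remaining columns one per taxon, cell values 0/1.
#'
#' @param path file path
#' @param provenance provenance tag used when reading
#' @return `read_incidence_csv()` returns a `community_matrix`.
#' @export
read_incidence_csv <- function(path, provenance = "truth") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  community_matrix(m, provenance)
}

#' @rdname read_incidence_csv
#' @param m a `community_matrix` to write
#' @export
write_incidence_csv <- function(m, path) {
  df <- data.frame(site_id = rownames(m), as.data.frame(unclass(m)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_incidence_csv
#' @param pool a species-pool data.frame to write (`taxon_id`, `habitat`)
#' @export
write_pool_csv <- function(pool, path) {
  utils::write.csv(pool, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
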