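# River networks: rooted trees of reaches with Strahler orders, Horton
# stream counts, catchment areas and along-stream distances.
#
# A reach is an edge of the dendritic network; its "site" is the point at its
# downstream node. Sampling locations are therefore named by reach id, and
# "upstream of x" includes x's own reach. Reaches may carry a barrier flag
# (e.g. a lake outflow): traversal for both catchment area and eDNA transport
# includes the barrier reach itself but nothing above it.

#' Build a validated river network from an edge list
#'
#' @param edges a data.frame with columns `reach_id`, `downstream_id`
#'   (`NA` or `""` for the single outlet), `length_km` (> 0),
#'   `subcatchment_area_km2` (>= 0) and optionally `barrier` (logical or 0/1).
#' @return an object of class `river_network`: the validated reach table with
#'   Strahler orders plus derived indices (children map, root id).
#' @details Validation rejects duplicate ids, zero or multiple outlets,
#'   dangling downstream references, cycles and non-positive lengths, naming
#'   the offending reach. Strahler orders follow the standard rule: headwater
#'   reaches have order 1; a reach's order is the maximum of its children's
#'   orders, incremented by one when that maximum is attained by at least two
#'   children.
#' @examples
#' y <- build_network(data.frame(
#'   reach_id = c("B", "C", "A"), downstream_id = c("A", "A", NA),
#'   length_km = c(1, 1, 1), subcatchment_area_km2 = c(1, 2, 3)))
#' strahler_orders(y)
#' @export
build_network <- function(edges) {
  req <- c("reach_id", "downstream_id", "length_km", "subcatchment_area_km2")
  if (!is.data.frame(edges) || !all(req %in% names(edges)))
    stop("edges must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  id <- as.character(edges$reach_id)
  down <- as.character(edges$downstream_id)
  down[is.na(down) | down == ""] <- NA_character_
  len <- as.numeric(edges$length_km)
  area <- as.numeric(edges$subcatchment_area_km2)
  barrier <- if ("barrier" %in% names(edges)) as.logical(edges$barrier) else
    rep(FALSE, length(id))
  barrier[is.na(barrier)] <- FALSE

  if (anyDuplicated(id))
    abort_reach("duplicate reach id", id[duplicated(id)][1L])
  n_out <- sum(is.na(down))
  if (n_out == 0L) stop("no outlet: every reach has a downstream id", call. = FALSE)
  if (n_out > 1L)
    stop(sprintf("multiple outlets: %s",
                 paste(id[is.na(down)], collapse = ", ")), call. = FALSE)
  dangling <- !is.na(down) & !(down %in% id)
  if (any(dangling))
    abort_reach(sprintf("downstream id '%s' does not exist", down[dangling][1L]),
                id[dangling][1L])
  if (any(!is.finite(len) | len <= 0))
    abort_reach("non-positive or missing length", id[!is.finite(len) | len <= 0][1L])
  if (any(!is.finite(area) | area < 0))
    abort_reach("negative or missing subcatchment area",
                id[!is.finite(area) | area < 0][1L])

  reaches <- data.frame(reach_id = id, downstream_id = down,
                        length_km = len, subcatchment_area_km2 = area,
                        barrier = barrier, stringsAsFactors = FALSE)
  rownames(reaches) <- id

  # Cycle / connectivity check: walk downstream from every reach.
  idx <- stats::setNames(seq_along(id), id)
  n <- length(id)
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (!is.na(down[j])) {
      if (seen[j]) abort_reach("cycle detected in downstream links", id[i])
      seen[j] <- TRUE
      j <- idx[[down[j]]]
    }
  }

  net <- structure(list(reaches = reaches,
                        children = split(id[!is.na(down)], down[!is.na(down)])),
                   class = "river_network")
  net$reaches$strahler_order <- unname(strahler_orders(net)[id])
  net
}

#' Strahler stream orders of every reach
#'
#' @param net a `river_network`
#' @return named integer vector, reach id -> order
#' @export
strahler_orders <- function(net) {
  stopifnot(inherits(net, "river_network"))
  id <- net$reaches$reach_id
  ord <- stats::setNames(rep(NA_integer_, length(id)), id)
  # process reaches in upstream-to-downstream topological order
  for (r in topo_order(net)) {
    kids <- net$children[[r]]
    if (is.null(kids) || length(kids) == 0L) {
      ord[[r]] <- 1L
    } else {
      ko <- ord[kids]
      m <- max(ko)
      ord[[r]] <- if (sum(ko == m) >= 2L) m + 1L else m
    }
  }
  ord
}

# reaches sorted leaves-first (children before parents)
topo_order <- function(net) {
  id <- net$reaches$reach_id
  down <- stats::setNames(net$reaches$downstream_id, id)
  depth <- stats::setNames(integer(length(id)), id)
  for (r in id) {
    d <- 0L
    j <- r
    while (!is.na(down[[j]])) {
      d <- d + 1L
      j <- down[[j]]
    }
    depth[[r]] <- d
  }
  id[order(-depth)]
}

#' Count maximal connected streams of each Strahler order
#'
#' A "stream" of order y is a maximal chain of contiguous order-y reaches.
#' Generated Horton networks satisfy \eqn{N_y = R_B^{\Omega - y}} exactly.
#'
#' @param net a `river_network`
#' @return named integer vector `N_y`, index = order
#' @export
stream_counts <- function(net) {
  stopifnot(inherits(net, "river_network"))
  ord <- stats::setNames(net$reaches$strahler_order, net$reaches$reach_id)
  down <- stats::setNames(net$reaches$downstream_id, net$reaches$reach_id)
  # a stream "ends" where the downstream reach has a different order (or outlet)
  ends <- vapply(names(ord), function(r) {
    d <- down[[r]]
    is.na(d) || ord[[d]] != ord[[r]]
  }, logical(1))
  tab <- table(factor(ord[ends], levels = seq_len(max(ord))))
  stats::setNames(as.integer(tab), seq_len(max(ord)))
}

#' Generate a Horton-law dendritic network
#'
#' Deterministic Horton topology: the single order-\eqn{\Omega} stream is fed
#' by exactly `bifurcation_ratio` streams of order \eqn{\Omega - 1}, and so on
#' recursively, so stream counts satisfy \eqn{N_y = R_B^{\Omega - y}} exactly.
#' Reach lengths and subcatchment areas are drawn log-normally around the
#' requested means with coefficient of variation `cv`.
#'
#' @param max_order maximum Strahler order \eqn{\Omega >= 1}
#' @param bifurcation_ratio integer \eqn{R_B >= 2}
#' @param mean_reach_length mean reach length, km
#' @param mean_subcatchment_area mean subcatchment area, km^2
#' @param cv coefficient of variation of the log-normal length/area draws
#' @param seed integer seed; the same seed reproduces the network exactly
#' @return a `river_network`
#' @export
generate_horton_network <- function(max_order, bifurcation_ratio = 2L,
                                    mean_reach_length = 1,
                                    mean_subcatchment_area = 1,
                                    cv = 0.3, seed = 1L) {
  if (max_order < 1) stop("max_order must be >= 1", call. = FALSE)
  rb <- bifurcation_ratio
  if (rb != as.integer(rb) || rb < 2)
    stop("bifurcation_ratio must be an integer >= 2", call. = FALSE)
  rb <- as.integer(rb)

  ids <- character(0); downs <- character(0)
  counter <- 0L
  new_id <- function(order) {
    counter <<- counter + 1L
    sprintf("s%d_o%d", counter, order)
  }
  # recursively attach rb feeder streams of order-1 below `order` to `parent`
  grow <- function(order, parent) {
    me <- new_id(order)
    ids <<- c(ids, me); downs <<- c(downs, parent)
    if (order > 1L) for (k in seq_len(rb)) grow(order - 1L, me)
    me
  }
  grow(as.integer(max_order), NA_character_)

  n <- length(ids)
  set.seed(split_seed(seed, 0L, stream = 1L))
  sdlog <- sqrt(log(1 + cv^2))
  rln <- function(m) stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  build_network(data.frame(reach_id = ids, downstream_id = downs,
                           length_km = rln(mean_reach_length),
                           subcatchment_area_km2 = rln(mean_subcatchment_area),
                           stringsAsFactors = FALSE))
}

#' Set of reaches draining to a reach (inclusive), honouring barriers
#'
#' @param net a `river_network`
#' @param x reach id
#' @param barrier_aware if `TRUE` (default), a barrier reach is included but
#'   its own upstream reaches are not traversed
#' @return character vector of reach ids, including `x`
#' @export
upstream_reaches <- function(net, x, barrier_aware = TRUE) {
  check_reach(net, x)
  barrier <- stats::setNames(net$reaches$barrier, net$reaches$reach_id)
  out <- character(0)
  frontier <- x
  while (length(frontier)) {
    out <- c(out, frontier)
    # x itself, even if flagged, is expanded: a barrier blocks what lies
    # above it from points further downstream, not its own sampling point
    expand <- frontier[!(barrier_aware & barrier[frontier]) | frontier == x]
    frontier <- unlist(lapply(expand, function(r) net$children[[r]]),
                       use.names = FALSE)
    frontier <- frontier %||% character(0)
  }
  unique(out)
}

#' Cumulative catchment area above (and including) a reach
#'
#' Sum of the subcatchment areas of every reach draining to `x`, including
#' `x`'s own. Reaches upstream of a barrier (e.g. a lake) are excluded.
#'
#' @inheritParams upstream_reaches
#' @return area in km^2
#' @export
cumulative_catchment_area <- function(net, x, barrier_aware = TRUE) {
  up <- upstream_reaches(net, x, barrier_aware = barrier_aware)
  sum(net$reaches[up, "subcatchment_area_km2"])
}

check_reach <- function(net, x) {
  stopifnot(inherits(net, "river_network"))
  bad <- setdiff(x, net$reaches$reach_id)
  if (length(bad)) abort_reach("unknown reach id", bad[1L])
  invisible(TRUE)
}

# downstream chain of reach ids from a site's reach (exclusive) to the root
root_path <- function(net, x) {
  down <- stats::setNames(net$reaches$downstream_id, net$reaches$reach_id)
  path <- character(0)
  j <- down[[x]]
  while (!is.na(j)) {
    path <- c(path, j)
    j <- down[[j]]
  }
  path
}

#' Along-stream distance between two sampling sites
#'
#' Sites sit at the downstream node of their named reach. The distance is the
#' sum of reach lengths along the unique tree path between the two points;
#' it is symmetric and `along_stream_distance(net, a, a) == 0`.
#'
#' @param net a `river_network`
#' @param a,b reach ids naming the two sites
#' @return distance in km
#' @seealso [flow_connected()]
#' @export
along_stream_distance <- function(net, a, b) {
  check_reach(net, c(a, b))
  if (a == b) return(0)
  len <- stats::setNames(net$reaches$length_km, net$reaches$reach_id)
  pa <- root_path(net, a)
  pb <- root_path(net, b)
  # strip the common downstream chain (common suffix of the two root paths)
  while (length(pa) && length(pb) &&
         pa[length(pa)] == pb[length(pb)]) {
    pa <- pa[-length(pa)]
    pb <- pb[-length(pb)]
  }
  sum(len[pa]) + sum(len[pb])
}

#' Is one site on the downstream flow path of the other?
#'
#' `TRUE` iff water (and hence eDNA) released at one of the two sites passes
#' the other, i.e. one reach is an ancestor-or-self of the other in the
#' drainage tree. Two sibling tributaries are not flow connected.
#'
#' @inheritParams along_stream_distance
#' @return logical
#' @export
flow_connected <- function(net, a, b) {
  check_reach(net, c(a, b))
  if (a == b) return(TRUE)
  (b %in% root_path(net, a)) || (a %in% root_path(net, b))
}

#' All-pairs along-stream distance matrix for a set of sites
#'
#' @param net a `river_network`
#' @param sites reach ids (default: all reaches)
#' @return symmetric matrix of km distances with site ids as dimnames
#' @export
distance_matrix <- function(net, sites = net$reaches$reach_id) {
  check_reach(net, sites)
  n <- length(sites)
  d <- matrix(0, n, n, dimnames = list(sites, sites))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- along_stream_distance(net, sites[i], sites[j])
  }
  d
}

#' @export
print.river_network <- function(x, ...) {
  r <- x$reaches
  cat(sprintf("river_network: %d reaches, outlet '%s', max Strahler order %d\n",
              nrow(r), r$reach_id[is.na(r$downstream_id)],
              max(r$strahler_order)))
  cat(sprintf("total length %.2f km, total subcatchment area %.2f km^2",
              sum(r$length_km), sum(r$subcatchment_area_km2)))
  if (any(r$barrier)) cat(sprintf(", barriers: %s",
                                  paste(r$reach_id[r$barrier], collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' @export
summary.river_network <- function(object, ...) {
  r <- object$reaches
  out <- list(n_reaches = nrow(r),
              outlet = r$reach_id[is.na(r$downstream_id)],
              max_order = max(r$strahler_order),
              stream_counts = stream_counts(object),
              total_length_km = sum(r$length_km),
              total_area_km2 = sum(r$subcatchment_area_km2))
  class(out) <- "summary.river_network"
  out
}

#' @export
print.summary.river_network <- function(x, ...) {
  cat(sprintf("river_network: %d reaches, outlet '%s'\n", x$n_reaches, x$outlet))
  cat("stream counts N_y by Strahler order:\n")
  print(x$stream_counts)
  cat(sprintf("total length %.2f km, total area %.2f km^2\n",
              x$total_length_km, x$total_area_km2))
  invisible(x)
}

#' Read / write the network edge-list TSV
#'
#' Columns: `reach_id`, `downstream_id` (empty for the outlet), `length_km`,
#' `subcatchment_area_km2`, optional `barrier` (0/1). Header required, UTF-8,
#' "." decimal separator.
#'
#' @param path file path
#' @return `read_network_tsv()` returns a `river_network`.
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(reach_id = "character",
                                         downstream_id = "character"))
  build_network(df)
}

#' @rdname read_network_tsv
#' @param net a `river_network` to write
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "river_network"))
  df <- net$reaches[, c("reach_id", "downstream_id", "length_km",
                        "subcatchment_area_km2", "barrier")]
  df$barrier <- as.integer(df$barrier)
  df$downstream_id[is.na(df$downstream_id)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
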