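# Statistical comparison of sampling methods: richness, taxon-area
# regression, ANCOVA, Jaccard dissimilarity, Mantel tests on flow-connected
# sites, and transport-scale estimation from the eDNA distance decay.

#' Per-site taxon richness (alpha-diversity)
#'
#' @param m a binary site-by-taxon matrix
#' @return named integer vector of row sums
#' @export
alpha_richness <- function(m) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1)))
    stop("incidence matrix must be binary", call. = FALSE)
  rs <- rowSums(m)
  storage.mode(rs) <- "integer"
  rs
}

#' Jaccard dissimilarity matrix between sites
#'
#' `D(a, b) = 1 - |A intersect B| / |A union B|` on the taxon sets of each
#' pair of rows. Pairs in which both communities are empty are undefined and
#' returned as `NA` with a warning; they are excluded from downstream
#' analyses.
#'
#' @param m binary site-by-taxon matrix
#' @return symmetric dissimilarity matrix with zero diagonal
#' @export
jaccard_matrix <- function(m) {
  m <- as.matrix(unclass(m))
  if (!all(m %in% c(0, 1)))
    stop("incidence matrix must be binary", call. = FALSE)
  D <- as.matrix(suppressWarnings(
    vegan::vegdist(m, method = "jaccard", binary = TRUE)))
  empty <- rowSums(m) == 0
  if (sum(empty) >= 2) {
    warning("Jaccard undefined for pairs of empty communities; returned NA",
            call. = FALSE)
    D[empty, empty] <- NA_real_
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

#' Taxon-area relationship: log10-log10 OLS regression
#'
#' Regresses `log10(richness)` on `log10(area)` by ordinary least squares.
#'
#' @param richness per-site taxon counts (all >= 1)
#' @param areas per-site cumulative catchment areas, km^2 (all > 0)
#' @return a list of class `taxon_area_fit`: `slope`, `intercept`,
#'   `r_squared`, `F_statistic`, `df_num`, `df_den`, `p_value`, and the
#'   underlying `lm` fit
#' @export
taxon_area_regression <- function(richness, areas) {
  if (length(richness) != length(areas) || length(richness) < 3)
    stop("need >= 3 sites with matching richness and area", call. = FALSE)
  bad <- which(richness < 1)
  if (length(bad))
    stop(sprintf("richness must be >= 1 for log10 (site %s)",
                 paste(names(richness)[bad] %||% bad, collapse = ", ")),
         call. = FALSE)
  bad <- which(areas <= 0)
  if (length(bad))
    stop(sprintf("areas must be > 0 for log10 (site %s)",
                 paste(names(areas)[bad] %||% bad, collapse = ", ")),
         call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = log10(areas),
                                            y = log10(richness)))
  sm <- suppressWarnings(summary(fit)) # noiseless input warns of a perfect fit
  n <- length(richness)
  if (is.null(sm$fstatistic)) {
    # constant response: slope 0, no variance to explain
    fs <- c(NA_real_, 1, n - 2)
    p <- NA_real_
    r2 <- NA_real_
  } else {
    fs <- sm$fstatistic
    p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    r2 <- sm$r.squared
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 F_statistic = unname(fs[1]),
                 df_num = unname(fs[2]),
                 df_den = unname(fs[3]),
                 p_value = unname(p),
                 fit = fit),
            class = "taxon_area_fit")
}

#' @export
print.taxon_area_fit <- function(x, ...) {
  cat(sprintf(
    "taxon-area fit: slope %.4f, intercept %.4f, r^2 %.3f, F(%d,%d) = %.3f, p = %.4g\n",
    x$slope, x$intercept, x$r_squared, x$df_num, x$df_den, x$F_statistic,
    x$p_value))
  invisible(x)
}

#' ANCOVA comparison of two regression lines
#'
#' Compares the taxon-area regressions of two groups (e.g. eDNA vs kicknet).
#' The slope test is the F-test of the group-by-covariate interaction in the
#' full two-line model; the intercept test is the F-test of the group effect
#' in the common-slope model. With 8 points per group the degrees of freedom
#' are (1, 12) and (1, 13) respectively.
#'
#' @param group_a,group_b data.frames (or lists) with numeric `x` and `y`
#' @return a list of class `ancova_result` with components `slope_test` and
#'   `intercept_test` (each `F`, `df_num`, `df_den`, `p_value`) and a
#'   `groups` table of per-group slopes and intercepts
#' @export
ancova_compare <- function(group_a, group_b) {
  ga <- as.data.frame(group_a); gb <- as.data.frame(group_b)
  if (nrow(ga) < 3 || nrow(gb) < 3)
    stop("need >= 3 points per group", call. = FALSE)
  if (stats::var(ga$x) == 0 || stats::var(gb$x) == 0)
    stop("degenerate covariate: zero variance within a group", call. = FALSE)
  dat <- rbind(data.frame(x = ga$x, y = ga$y, g = "A"),
               data.frame(x = gb$x, y = gb$y, g = "B"))
  dat$g <- factor(dat$g)
  full <- stats::lm(y ~ x * g, data = dat)       # separate slopes
  common <- stats::lm(y ~ x + g, data = dat)     # common slope
  nocov <- stats::lm(y ~ x, data = dat)          # no group effect

  slope_aov <- stats::anova(common, full)
  int_aov <- stats::anova(nocov, common)
  per_group <- do.call(rbind, lapply(split(dat, dat$g), function(d) {
    cf <- stats::coef(stats::lm(y ~ x, data = d))
    data.frame(intercept = unname(cf[1]), slope = unname(cf[2]))
  }))
  structure(list(
    slope_test = list(F = slope_aov$F[2], df_num = as.integer(slope_aov$Df[2]),
                      df_den = as.integer(slope_aov$Res.Df[2]),
                      p_value = slope_aov$`Pr(>F)`[2]),
    intercept_test = list(F = int_aov$F[2], df_num = as.integer(int_aov$Df[2]),
                          df_den = as.integer(int_aov$Res.Df[2]),
                          p_value = int_aov$`Pr(>F)`[2]),
    groups = per_group), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  st <- x$slope_test; it <- x$intercept_test
  cat(sprintf("ANCOVA slope test:     F(%d,%d) = %.4f, p = %.4g\n",
              st$df_num, st$df_den, st$F, st$p_value))
  cat(sprintf("ANCOVA intercept test: F(%d,%d) = %.4f, p = %.4g\n",
              it$df_num, it$df_den, it$F, it$p_value))
  print(round(x$groups, 4))
  invisible(x)
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation over the strict upper triangles, with significance
#' from simultaneous row/column permutations of the second matrix. The
#' one-sided p-value for positive autocorrelation uses the
#' "include the observed" convention,
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_permutations)`, so p is never 0.
#'
#' @param d1,d2 symmetric matrices with matching site order, zero diagonal
#' @param n_permutations number of random permutations (default 9999)
#' @param seed integer seed making the permutation draw reproducible
#' @return a list of class `mantel_result`: `r`, `p_value`, `n_permutations`,
#'   `seed`
#' @export
mantel_test <- function(d1, d2, n_permutations = 9999, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!isTRUE(all.equal(dim(d1), dim(d2))) ||
      !is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("matrices must share dimensions and site order", call. = FALSE)
  if (!isSymmetric(unname(d1)) || !isSymmetric(unname(d2)))
    stop("matrices must be symmetric", call. = FALSE)
  if (nrow(d1) < 3) stop("need >= 3 sites", call. = FALSE)
  if (n_permutations < 1) stop("need >= 1 permutation", call. = FALSE)
  set.seed(split_seed(seed, 0L, stream = 6L))
  # permute switches to complete enumeration for small n; silence its notes
  v <- suppressMessages(suppressWarnings(
    vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                  method = "pearson", permutations = n_permutations)))
  structure(list(r = unname(v$statistic), p_value = v$signif,
                 n_permutations = n_permutations, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$r, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Maximal flow-connected chain of sampling sites
#'
#' Returns the largest subset of `sites` that is totally ordered by the
#' flow-connected relation and contains the outlet-most site: the mainstem
#' chain along which eDNA can actually travel from every member to the most
#' downstream member. Tributary sites, into which eDNA from the rest of the
#' network cannot flow, are excluded and reported.
#'
#' @param net a `river_network`
#' @param sites reach ids
#' @return list with `mainstem` (ordered downstream to upstream) and
#'   `excluded`
#' @export
flow_connected_subset <- function(net, sites) {
  check_reach(net, sites)
  if (length(sites) == 1L)
    return(list(mainstem = sites, excluded = character(0)))
  # ancestors-or-self of each site, restricted to the site set
  anc <- lapply(sites, function(s)
    intersect(c(s, root_path(net, s)), sites))
  names(anc) <- sites
  depth <- vapply(sites, function(s) length(root_path(net, s)), numeric(1))
  outlet_most <- sites[which.min(depth)]
  # each candidate chain is the within-set ancestry of one terminal site
  cand <- Filter(function(ch) outlet_most %in% ch, anc)
  sizes <- vapply(cand, length, integer(1))
  best <- cand[[order(-sizes, names(cand))[1]]]
  chain <- best[order(vapply(best, function(s) length(root_path(net, s)),
                             numeric(1)))]
  list(mainstem = chain, excluded = setdiff(sites, chain))
}
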