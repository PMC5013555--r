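# Small fixtures built in code.

# B and C join A (the outlet)
y_network <- function(lb = 1, lc = 1, la = 1, ab = 1, ac = 2, aa = 3) {
  build_network(data.frame(
    reach_id = c("B", "C", "A"),
    downstream_id = c("A", "A", NA),
    length_km = c(lb, lc, la),
    subcatchment_area_km2 = c(ab, ac, aa),
    stringsAsFactors = FALSE))
}

# sites B and C each sit one reach above the shared junction at the top of A:
# B -> P -> A <- Q <- C, with branch path lengths len(P), len(Q)
deep_sibling_network <- function(lp = 3, lq = 4) {
  build_network(data.frame(
    reach_id = c("B", "P", "C", "Q", "A"),
    downstream_id = c("P", "A", "Q", "A", NA),
    length_km = c(1, lp, 1, lq, 5),
    subcatchment_area_km2 = 1,
    stringsAsFactors = FALSE))
}

# linear chain r1 (headwater) -> r2 -> ... -> rn (outlet), unit areas
chain_network <- function(n, length_km = 1) {
  ids <- paste0("r", seq_len(n))
  build_network(data.frame(
    reach_id = ids,
    downstream_id = c(ids[-1], NA)[seq_len(n)],
    length_km = length_km,
    subcatchment_area_km2 = 1,
    stringsAsFactors = FALSE))
}

make_truth <- function(incidence, attachment = character(0)) {
  community_matrix(incidence, "truth", attachment = attachment)
}

# assignment-record rows with sensible defaults, overridable per field
make_records <- function(n = 1, family = "Baetidae", pct_identity = 95,
                         align_len_bp = 200, bit_score = 300,
                         superkingdom = "Eukaryota", env_sample = FALSE,
                         order = "Ephemeroptera", genus = "", species = "",
                         site_id = "mock") {
  if (n == 0) {
    return(make_records(1)[0, , drop = FALSE])
  }
  data.frame(sequence_id = sprintf("s%04d", seq_len(n)), site_id = site_id,
             phylum = "Arthropoda", class = "Insecta", order = order,
             family = family, genus = genus, species = species,
             pct_identity = pct_identity, align_len_bp = align_len_bp,
             bit_score = bit_score, superkingdom = superkingdom,
             env_sample = env_sample, stringsAsFactors = FALSE)
}

# random record table with a mix of passing/failing rows for property tests
random_records <- function(n, seed) {
  set.seed(seed)
  make_records(
    n,
    family = sample(c("Baetidae", "Perlidae", "", "Gammaridae"), n, TRUE),
    pct_identity = round(runif(n, 85, 100), 2),
    align_len_bp = sample(60:400, n, TRUE),
    bit_score = round(runif(n, 50, 600), 1),
    superkingdom = sample(c("Eukaryota", "Bacteria"), n, TRUE, c(.8, .2)),
    env_sample = sample(c(TRUE, FALSE), n, TRUE, c(.1, .9)))
}

# all permutations of 1..n (tiny n only), for exhaustive Mantel enumeration
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}
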