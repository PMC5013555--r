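# Quality control of metabarcoding taxonomic assignments.
#
# Operates on post-assignment record tables (one row per sequence, with its
# best-hit identity, alignment length, bit score and assigned lineage), not
# on raw reads. The exclusion rules are phrased strictly ("< 90.0 %
# similarity", "< 100 bp overlap", "bit score < 100"), so a record exactly at
# a threshold is retained.

RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Assignment-filter thresholds
#'
#' @param min_identity minimum best-hit percent identity (records below are
#'   excluded); default 90.0
#' @param min_alignment minimum alignment length with the query, bp; default 100
#' @param min_bitscore minimum bit score; default 100
#' @param required_rank lowest taxonomic rank that must be filled; records
#'   not named at (or below) this rank are excluded; default `"family"`
#' @param eukaryote_only exclude records whose best hit is not a eukaryote
#' @param exclude_environmental exclude records matching best with
#'   uncharacterised environmental samples
#' @return an object of class `filter_thresholds`
#' @export
filter_thresholds <- function(min_identity = 90.0, min_alignment = 100,
                              min_bitscore = 100, required_rank = "family",
                              eukaryote_only = TRUE,
                              exclude_environmental = TRUE) {
  stopifnot(min_identity >= 0, min_alignment >= 0, min_bitscore >= 0,
            required_rank %in% RANKS)
  structure(list(min_identity = min_identity, min_alignment = min_alignment,
                 min_bitscore = min_bitscore, required_rank = required_rank,
                 eukaryote_only = eukaryote_only,
                 exclude_environmental = exclude_environmental),
            class = "filter_thresholds")
}

check_records <- function(records) {
  req <- c("sequence_id", "family", "pct_identity", "align_len_bp",
           "bit_score", "superkingdom", "env_sample")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("assignment records lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- c("pct_identity", "align_len_bp", "bit_score")
  for (cl in num) {
    bad <- !is.finite(records[[cl]])
    if (any(bad))
      stop(sprintf("malformed record: non-finite %s (sequence '%s')", cl,
                   records$sequence_id[bad][1L]), call. = FALSE)
  }
  invisible(TRUE)
}

rank_filled <- function(records, rank) {
  ranks_here <- intersect(RANKS, names(records))
  at_or_below <- ranks_here[seq(match(rank, ranks_here), length(ranks_here))]
  Reduce(`|`, lapply(at_or_below, function(r) {
    v <- records[[r]]
    !is.na(v) & v != ""
  }))
}

#' Apply assignment filters with a per-criterion exclusion audit
#'
#' A record is retained iff it passes every criterion; the audit attributes
#' each dropped record to every criterion it fails, so audit counts can
#' exceed the number of dropped records, while
#' `n_retained + n_excluded == n_input` always holds.
#'
#' @param records assignment-record data.frame (see [read_assignments_tsv()])
#' @param thresholds a [filter_thresholds()] object
#' @param blocklist character vector of taxa (matched against the lowest
#'   filled rank and against `family`) excluded after filtering, e.g.
#'   suspected reagent contaminants
#' @return list with `retained` (data.frame), `audit` (named exclusion counts
#'   per criterion plus `n_input`, `n_retained`, `n_excluded`)
#' @export
apply_assignment_filters <- function(records, thresholds = filter_thresholds(),
                                     blocklist = character(0)) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (nrow(records) == 0L) {
    audit <- c(identity = 0L, alignment = 0L, bitscore = 0L, rank = 0L,
               non_eukaryote = 0L, environmental = 0L, blocklist = 0L,
               n_input = 0L, n_retained = 0L, n_excluded = 0L)
    return(list(retained = records, audit = audit))
  }
  check_records(records)
  fail <- list(
    identity = records$pct_identity < thresholds$min_identity,
    alignment = records$align_len_bp < thresholds$min_alignment,
    bitscore = records$bit_score < thresholds$min_bitscore,
    rank = !rank_filled(records, thresholds$required_rank),
    non_eukaryote = if (thresholds$eukaryote_only)
      records$superkingdom != "Eukaryota" else rep(FALSE, nrow(records)),
    environmental = if (thresholds$exclude_environmental)
      as.logical(records$env_sample) else rep(FALSE, nrow(records)))
  any_fail <- Reduce(`|`, fail)
  # blocklist applies after the quality filters, to otherwise-retained records
  blocked <- !any_fail & (records$family %in% blocklist |
                            lowest_taxon(records) %in% blocklist)
  retained <- records[!any_fail & !blocked, , drop = FALSE]
  audit <- c(vapply(fail, sum, integer(1)), blocklist = sum(blocked),
             n_input = nrow(records), n_retained = nrow(retained),
             n_excluded = nrow(records) - nrow(retained))
  list(retained = retained, audit = audit)
}

# lowest filled rank name of each record (e.g. species if present, else genus...)
lowest_taxon <- function(records) {
  ranks_here <- intersect(RANKS, names(records))
  out <- rep(NA_character_, nrow(records))
  for (r in ranks_here) { # coarse to fine; later overwrites earlier
    v <- records[[r]]
    filled <- !is.na(v) & v != ""
    out[filled] <- v[filled]
  }
  out
}

#' Geographic verification of detected taxa against country checklists
#'
#' A taxon is retained iff it is known from Switzerland (CH), or known from
#' all four neighbouring countries (AT, FR, DE, IT) and not on the explicit
#' exclusion list. Taxa absent from the checklist are dropped as
#' unverifiable. Pure function of the checklist: input order never changes
#' the retained set.
#'
#' @param taxa character vector of taxon names
#' @param checklist data.frame with columns `taxon`, `CH`, `AT`, `FR`, `DE`,
#'   `IT` (0/1) and `excluded` (0/1)
#' @return list with `retained` (character) and `dropped` (data.frame of
#'   `taxon`, `reason`)
#' @export
geographic_verify <- function(taxa, checklist) {
  req <- c("taxon", "CH", "AT", "FR", "DE", "IT", "excluded")
  stopifnot(all(req %in% names(checklist)))
  taxa <- unique(taxa)
  idx <- match(taxa, checklist$taxon)
  reason <- rep(NA_character_, length(taxa))
  reason[is.na(idx)] <- "unverifiable"
  known <- which(!is.na(idx))
  for (i in known) {
    row <- checklist[idx[i], ]
    if (row$CH == 1) next
    if (row$AT == 1 && row$FR == 1 && row$DE == 1 && row$IT == 1) {
      if (row$excluded == 1) reason[i] <- "excluded"
    } else reason[i] <- "not in CH nor all four neighbours"
  }
  list(retained = taxa[is.na(reason)],
       dropped = data.frame(taxon = taxa[!is.na(reason)],
                            reason = reason[!is.na(reason)],
                            stringsAsFactors = FALSE))
}

#' Mock-community validation metrics
#'
#' Sequence-level accuracy and taxon-level false-positive rate of retained
#' assignments against the known mock-community composition. The
#' false-positive denominator is the number of mock taxa detected after
#' filtering; percentages are rounded to 2 decimals for display only.
#'
#' @param records retained assignment records
#' @param truth character vector: families composing the mock community
#' @param taxon_col column holding the assigned taxon (default `"family"`)
#' @return list of class `mock_metrics`: `n_sequences`,
#'   `pct_sequences_correct`, `pct_sequences_incorrect`, `n_taxa_detected`
#'   (mock taxa detected), `n_false_positive_taxa`,
#'   `taxon_false_positive_rate` (percent), `detected_taxa`,
#'   `false_positive_taxa`
#' @export
mock_metrics <- function(records, truth, taxon_col = "family") {
  if (length(truth) == 0L) stop("empty mock-community truth", call. = FALSE)
  if (nrow(records) == 0L) stop("no retained records", call. = FALSE)
  tx <- records[[taxon_col]]
  detected <- unique(tx)
  in_truth <- detected %in% truth
  n_correct <- sum(tx %in% truth)
  n_det <- sum(in_truth)
  n_fp <- sum(!in_truth)
  structure(list(
    n_sequences = nrow(records),
    pct_sequences_correct = 100 * n_correct / nrow(records),
    pct_sequences_incorrect = 100 * (nrow(records) - n_correct) / nrow(records),
    n_taxa_detected = n_det,
    n_false_positive_taxa = n_fp,
    taxon_false_positive_rate = 100 * n_fp / n_det,
    detected_taxa = sort(detected[in_truth]),
    false_positive_taxa = sort(detected[!in_truth])),
    class = "mock_metrics")
}

#' @export
print.mock_metrics <- function(x, ...) {
  cat(sprintf("mock community: %d sequences, %.2f%% correct, %.2f%% incorrect\n",
              x$n_sequences, round(x$pct_sequences_correct, 2),
              round(x$pct_sequences_incorrect, 2)))
  cat(sprintf("%d mock taxa detected, %d false-positive taxa (rate %.1f%%)\n",
              x$n_taxa_detected, x$n_false_positive_taxa,
              x$taxon_false_positive_rate))
  invisible(x)
}

#' Identity-threshold sweep on a mock community
#'
#' Re-filters the records at each identity threshold and tracks the
#' taxon-level error trade-off: raising the threshold removes false-positive
#' taxa but introduces false absences. The primary false-absence rate uses
#' mock taxa detected at the base threshold as denominator; a secondary rate
#' against the full mock composition is also reported.
#'
#' @param records assignment records (pre-filtering)
#' @param truth mock-community families
#' @param identity_grid identity thresholds to evaluate, within \[0, 100\]
#' @param base_thresholds the base [filter_thresholds()] defining which taxa
#'   count as "detected at base"
#' @param taxon_col column holding the assigned taxon
#' @return data.frame with one row per threshold: `threshold`,
#'   `n_retained_sequences`, `n_taxa_detected`, `fp_rate` (percent, among
#'   taxa detected at that threshold), `false_absence_rate` (percent of
#'   base-detected mock taxa lost), `false_absence_rate_vs_truth` (percent of
#'   all mock taxa undetected)
#' @export
threshold_sweep <- function(records, truth, identity_grid = seq(90, 99, by = 1),
                            base_thresholds = filter_thresholds(),
                            taxon_col = "family") {
  stopifnot(all(identity_grid >= 0), all(identity_grid <= 100))
  base <- apply_assignment_filters(records, base_thresholds)$retained
  base_detected <- intersect(unique(base[[taxon_col]]), truth)
  rows <- lapply(identity_grid, function(t) {
    th <- base_thresholds
    th$min_identity <- max(t, base_thresholds$min_identity)
    kept <- apply_assignment_filters(records, th)$retained
    det <- unique(kept[[taxon_col]])
    det_truth <- intersect(det, truth)
    lost <- setdiff(base_detected, det_truth)
    data.frame(
      threshold = t,
      n_retained_sequences = nrow(kept),
      n_taxa_detected = length(det_truth),
      fp_rate = if (length(det_truth)) 100 * length(setdiff(det, truth)) /
        length(det_truth) else NA_real_,
      false_absence_rate = if (length(base_detected))
        100 * length(lost) / length(base_detected) else NA_real_,
      false_absence_rate_vs_truth = 100 * length(setdiff(truth, det_truth)) /
        length(truth))
  })
  do.call(rbind, rows)
}

#' Detection overlap between eDNA and kicknet methods
#'
#' Partitions the union of taxa detected anywhere by either method.
#'
#' @param edna,kicknet `community_matrix` objects (or binary matrices) over
#'   a shared taxon naming convention
#' @return list: `n_both`, `n_edna_only`, `n_kicknet_only`, `n_total`
#' @export
method_overlap <- function(edna, kicknet) {
  det <- function(m) colnames(m)[colSums(as.matrix(unclass(m))) > 0]
  de <- det(edna); dk <- det(kicknet)
  list(n_both = length(intersect(de, dk)),
       n_edna_only = length(setdiff(de, dk)),
       n_kicknet_only = length(setdiff(dk, de)),
       n_total = length(union(de, dk)))
}

#' Per-phylum habitat partition of detected species
#'
#' @param species_table data.frame with columns `phylum` and `habitat`
#'   (`"terrestrial"` / `"freshwater"`), one row per verified species
#' @return data.frame per phylum: `n_species`, `pct_terrestrial`,
#'   `pct_freshwater` (summing to 100 within rounding)
#' @export
habitat_partition <- function(species_table) {
  stopifnot(all(c("phylum", "habitat") %in% names(species_table)))
  lab <- species_table$habitat
  bad <- is.na(lab) | !(lab %in% c("terrestrial", "freshwater"))
  if (any(bad)) {
    id <- species_table$species %||% species_table$taxon_id %||%
      rownames(species_table)
    stop("unlabeled or mislabeled species: ",
         paste(utils::head(id[bad], 5), collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(species_table, species_table$phylum),
                               function(d) {
    data.frame(phylum = d$phylum[1], n_species = nrow(d),
               pct_terrestrial = 100 * mean(d$habitat == "terrestrial"),
               pct_freshwater = 100 * mean(d$habitat == "freshwater"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read an assignment-record TSV
#'
#' Columns: `sequence_id`, `site_id`, the lineage ranks `phylum` ... `species`
#' (empty string = unassigned rank), `pct_identity`, `align_len_bp`,
#' `bit_score`, `superkingdom`, `env_sample` (0/1).
#'
#' @param path file path
#' @return data.frame of assignment records
#' @export
read_assignments_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  df$env_sample <- as.logical(df$env_sample)
  check_records(df)
  df
}

#' Packaged synthetic species-habitat table
#'
#' A synthetic stand-in for the geographically verified species list of the
#' Glatt study: 255 species across seven phyla, each labelled terrestrial or
#' freshwater. The per-phylum composition is illustrative, not the study's.
#'
#' @return data.frame with columns `species`, `phylum`, `habitat`
#' @export
glatt_species_synthetic <- function() {
  path <- system.file("extdata", "glatt_species_synthetic.csv",
                      package = "ednariver", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a geographic checklist CSV
#'
#' Columns: `taxon`, `CH`, `AT`, `FR`, `DE`, `IT` (0/1), `excluded` (0/1).
#'
#' @param path file path
#' @return checklist data.frame
#' @export
read_checklist_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
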