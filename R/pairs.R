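#' Read a feature coordinate table
#'
#' Accepts either a TSV with header (`id`, `chrom`, `position`, optional flag
#' columns) or a BED file (0-based half-open; read via `rtracklayer` and
#' collapsed to the interval midpoint). Gene tables use the TSS as the
#' position; gRNA tables use the target-site midpoint.
#'
#' @param path File path; format inferred from the `.bed` extension unless
#'   `format` is given.
#' @param format `"auto"`, `"tsv"`, or `"bed"`.
#' @return Data.frame with at least `id`, `chrom`, `position`.
#' @export
read_feature_table <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading BED requires the rtracklayer package")
    }
    gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
    data.frame(
      id = if (!is.null(gr$name)) gr$name else paste0("feature", seq_len(nrow(gr))),
      chrom = as.character(gr$seqnames),
      position = floor((gr$start + gr$end) / 2),
      stringsAsFactors = FALSE
    )
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("id", "chrom", "position") %in% names(df)))
    df
  }
}

#' Construct candidate cis gene-gRNA pairs
#'
#' Pairs each protein-coding gene with each candidate-enhancer gRNA whose
#' target site lies within `window` base pairs of the gene's TSS on the same
#' chromosome (inclusive at exactly `window`). Distance is
#' `|site midpoint - TSS|`; strand is ignored.
#'
#' @param genes Data.frame: `id`, `chrom`, `position` (TSS), optional logical
#'   `protein_coding` (missing means all genes qualify).
#' @param grnas Data.frame: `id`, `chrom`, `position` (target midpoint),
#'   optional `class` column — only `"candidate_enhancer"` rows are paired
#'   when present.
#' @param window Window half-width in bp (default 1 Mb).
#' @return Data.frame `gene_id`, `grna_id`, `distance`,
#'   `pair_type = "cis_candidate"`, ordered by gene then gRNA ID.
#' @export
make_cis_pairs <- function(genes, grnas, window = 1e6) {
  genes <- as.data.frame(genes); grnas <- as.data.frame(grnas)
  if ("protein_coding" %in% names(genes)) genes <- genes[as.logical(genes$protein_coding), ]
  if ("class" %in% names(grnas)) grnas <- grnas[grnas$class == "candidate_enhancer", ]
  shared <- union(genes$chrom, grnas$chrom)
  bad <- shared[is.na(shared) | shared == ""]
  if (length(bad)) stop("invalid chromosome names: ", paste(bad, collapse = ", "))
  merged <- merge(genes[, c("id", "chrom", "position")],
                  grnas[, c("id", "chrom", "position")],
                  by = "chrom", suffixes = c("_gene", "_grna"))
  merged$distance <- abs(merged$position_grna - merged$position_gene)
  merged <- merged[merged$distance <= window, , drop = FALSE]
  out <- data.frame(gene_id = merged$id_gene, grna_id = merged$id_grna,
                    distance = merged$distance, pair_type = "cis_candidate",
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$grna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct in-silico negative-control pairs
#'
#' Builds pairs expected to carry no regulatory signal: gRNAs whose target
#' sites lie strictly farther than `min_distance` from the TSS of every known
#' transcription-factor gene are paired only with non-TF genes on *other*
#' chromosomes, then uniformly downsampled to `genes_per_grna` genes per gRNA
#' under `seed`. TF genes are excluded because their trans effects could leak
#' signal into nominally null pairs.
#'
#' @param genes Data.frame: `id`, `chrom`, `position` (TSS).
#' @param grnas Data.frame: `id`, `chrom`, `position`.
#' @param tf_gene_ids Character vector of transcription-factor gene IDs
#'   (subset of `genes$id`).
#' @param min_distance Exclusion radius around TF TSSs in bp (default 1 Mb,
#'   strict inequality: a gRNA exactly at `min_distance` is excluded).
#' @param genes_per_grna Downsampling cap per gRNA (default 500).
#' @param seed Integer seed for the downsample.
#' @return Data.frame `gene_id`, `grna_id`, `pair_type = "neg_control"`.
#' @export
make_insilico_negative_pairs <- function(genes, grnas, tf_gene_ids,
                                         min_distance = 1e6,
                                         genes_per_grna = 500, seed = 1) {
  stopifnot(all(tf_gene_ids %in% genes$id))
  tf <- genes[genes$id %in% tf_gene_ids, , drop = FALSE]
  near_tf <- function(chrom, pos) {
    same <- tf[tf$chrom == chrom, , drop = FALSE]
    nrow(same) > 0 && any(abs(same$position - pos) <= min_distance)
  }
  eligible <- !mapply(near_tf, grnas$chrom, grnas$position)
  grnas_ok <- grnas[eligible, , drop = FALSE]
  candidate_genes <- genes[!(genes$id %in% tf_gene_ids), , drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(grnas_ok)), function(k) {
    pool <- candidate_genes$id[candidate_genes$chrom != grnas_ok$chrom[k]]
    if (length(pool) < genes_per_grna) {
      warning("gRNA ", grnas_ok$id[k], ": only ", length(pool),
              " eligible genes (< ", genes_per_grna, "); keeping all")
      chosen <- pool
    } else {
      chosen <- sample(pool, genes_per_grna)
    }
    data.frame(gene_id = chosen, grna_id = grnas_ok$id[k],
               pair_type = "neg_control", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene_id = character(), grna_id = character(),
                                      pair_type = character())
  rownames(out) <- NULL
  out
}

#' Kolmogorov-Smirnov uniformity diagnostic for p-values
#'
#' One-sample KS test of a p-value vector against Uniform(0, 1). Used to
#' check calibration of null (negative-control) p-values: a calibrated
#' method's null p-values should be indistinguishable from uniform.
#'
#' @param p_values Vector of p-values in (0, 1], length >= 5.
#' @return List: `statistic` (sup-distance), `p_value`.
#' @export
ks_uniformity <- function(p_values) {
  stopifnot(length(p_values) >= 5, all(p_values > 0 & p_values <= 1))
  kt <- suppressWarnings(ks.test(p_values, "punif"))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Flag miscalibrated groups by Bonferroni-corrected KS tests
#'
#' @param ks_p_values Per-group KS p-values (e.g. one per gene).
#' @param alpha Family-wise level (default 0.05).
#' @return Logical vector: group significantly deviates from uniformity at
#'   the Bonferroni threshold `alpha / G`, `G = length(ks_p_values)`.
#' @export
ks_flag <- function(ks_p_values, alpha = 0.05) {
  ks_p_values < alpha / length(ks_p_values)
}

#' Benjamini-Hochberg discovery calling
#'
#' Standard BH step-up at level `fdr`. Apply to the candidate-pair family
#' only: mixing in positive controls makes BH anticonservative.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @param fdr Target false discovery rate (default 0.1).
#' @return Logical rejection flags, same order as the input.
#' @export
bh_discoveries <- function(p_values, fdr = 0.1) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  p.adjust(p_values, method = "BH") <= fdr
}
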