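## Abundance and expression quantitation: RPKM for MAGs and Mash-clusters
## and percent normalized spectral abundance factors (%NSAF) for
## metaproteome spectral counts, plus linking of expressed proteins to
## representative SusC/D clusters.

#' Reads per kilobase per million (RPKM)
#'
#' RPKM = (mapped reads on MAG x 1e6) / (assembly length in kbp x total
#' reads in sample). Vectorised over \code{mapped_reads} and
#' \code{assembly_length_kbp}.
#'
#' @param mapped_reads reads mapped to the MAG.
#' @param assembly_length_kbp MAG assembly length in kilobase pairs.
#' @param total_reads total reads in the sample.
#' @return RPKM value(s).
#' @examples
#' rpkm(1000, 2000, 1e7)  # 0.05
#' @export
rpkm <- function(mapped_reads, assembly_length_kbp, total_reads) {
    if (any(assembly_length_kbp <= 0)) stop("assembly length must be > 0")
    if (any(total_reads <= 0)) stop("total reads must be > 0")
    if (any(mapped_reads < 0)) stop("negative mapped reads")
    if (any(mapped_reads > total_reads))
        stop("mapped reads exceed total reads")
    mapped_reads * 1e6 / (assembly_length_kbp * total_reads)
}

#' Mash-cluster abundance from representative MAGs
#'
#' The cluster's abundance is approximated by the arithmetic mean of its
#' (one or two) representatives' RPKM values.
#'
#' @param representative_rpkms numeric vector of length 1 or 2.
#' @return mean RPKM.
#' @export
clusterAbundance <- function(representative_rpkms) {
    if (!length(representative_rpkms) %in% c(1, 2))
        stop("expected 1 or 2 representative values")
    mean(representative_rpkms)
}

#' Percent normalized spectral abundance factor (%NSAF)
#'
#' \%NSAF_i = 100 * (SpC_i / L_i) / sum_j (SpC_j / L_j), so a protein
#' carrying 1 percent of the length-normalized spectral counts of a
#' proteome experiment receives a \%NSAF of exactly 1, and each column
#' sums to 100.
#'
#' @param spectral_counts non-negative counts (vector = one sample, or a
#'   proteins-by-samples matrix).
#' @param lengths protein lengths in residues.
#' @return \%NSAF values with the shape of \code{spectral_counts}.
#' @examples
#' nsaf(c(10, 10), c(100, 200))  # 66.67, 33.33
#' @export
nsaf <- function(spectral_counts, lengths) {
    if (any(lengths <= 0)) stop("protein lengths must be > 0")
    if (any(spectral_counts < 0)) stop("negative spectral counts")
    one <- function(cts) {
        saf <- cts / lengths
        tot <- sum(saf)
        if (tot == 0) stop("all-zero spectral counts: %NSAF undefined")
        100 * saf / tot
    }
    if (is.matrix(spectral_counts)) {
        if (nrow(spectral_counts) != length(lengths))
            stop("lengths must match rows of the count matrix")
        apply(spectral_counts, 2, one)
    } else {
        if (length(spectral_counts) != length(lengths))
            stop("counts and lengths differ in length")
        one(spectral_counts)
    }
}

#' Per-sample MAG abundance as a SummarizedExperiment
#'
#' Wraps mapped-read counts into a \code{SummarizedExperiment} with
#' \code{counts} and \code{rpkm} assays; sample metadata (date, bloom
#' phase, total reads) lives in \code{colData}, MAG lengths in
#' \code{rowData}.
#'
#' @param counts MAGs-by-samples matrix of mapped-read counts.
#' @param lengths_kbp per-MAG assembly length (kbp), named or in row
#'   order.
#' @param total_reads per-sample total read counts.
#' @param sampleData optional data.frame of additional per-sample
#'   metadata (e.g. \code{date}, \code{bloom_phase}).
#' @return a \link[SummarizedExperiment]{SummarizedExperiment}.
#' @export
abundanceMatrix <- function(counts, lengths_kbp, total_reads,
                            sampleData = NULL) {
    if (length(total_reads) != ncol(counts))
        stop("one total-read count per sample required")
    rk <- sweep(counts * 1e6, 1, lengths_kbp, "/")
    rk <- sweep(rk, 2, total_reads, "/")
    cd <- S4Vectors::DataFrame(total_reads = total_reads,
                               row.names = colnames(counts))
    if (!is.null(sampleData)) cd <- cbind(cd, S4Vectors::DataFrame(sampleData))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts, rpkm = rk),
        rowData = S4Vectors::DataFrame(length_kbp = lengths_kbp,
                                       row.names = rownames(counts)),
        colData = cd)
}

#' Per-sample proteome table as a SummarizedExperiment
#'
#' Wraps spectral counts into a \code{SummarizedExperiment} with
#' \code{counts} and \code{nsaf} assays. Technical duplicate columns (same
#' sample id) are merged first, by mean (default) or sum.
#'
#' @param counts proteins-by-runs matrix of spectral counts; column names
#'   are sample ids (duplicated names = technical duplicates).
#' @param lengths protein lengths (residues), in row order.
#' @param duplicates how to merge technical duplicates: \code{"mean"} or
#'   \code{"sum"}.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment}.
#' @export
proteomeTable <- function(counts, lengths, duplicates = c("mean", "sum")) {
    duplicates <- match.arg(duplicates)
    if (any(counts < 0) || any(counts != floor(counts)))
        stop("spectral counts must be non-negative integers")
    samples <- colnames(counts)
    if (is.null(samples)) samples <- as.character(seq_len(ncol(counts)))
    merged <- sapply(unique(samples), function(s) {
        sub <- counts[, samples == s, drop = FALSE]
        if (duplicates == "mean") rowMeans(sub) else rowSums(sub)
    })
    merged <- as.matrix(merged)
    rownames(merged) <- rownames(counts)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = merged, nsaf = nsaf(merged, lengths)),
        rowData = S4Vectors::DataFrame(length = lengths,
                                       row.names = rownames(counts)))
}

#' Link expressed proteins to representative SusC/D clusters
#'
#' Each expressed protein is linked to the representative cluster with the
#' highest global-alignment amino acid identity, provided that identity
#' reaches \code{aaLinkIdentity} (default 90 percent); lower-identity
#' proteins stay unlinked.
#'
#' @param expressed data.frame with columns \code{protein_id},
#'   \code{aa_sequence}, \code{sample}, \code{nsaf}.
#' @param clusters representative cluster table (from
#'   \code{\link{selectRepresentatives}}) with a
#'   \code{representative_gene} column.
#' @param genes gene table supplying \code{aa_sequence} for
#'   representatives.
#' @param config a \code{\link{pulConfig}}.
#' @return data.frame \code{protein_id}, \code{sample}, \code{nsaf},
#'   \code{cluster_id}, \code{aa_identity}; one row per linked protein.
#' @export
linkExpression <- function(expressed, clusters, genes,
                           config = pulConfig()) {
    reps <- clusters[clusters$representative, , drop = FALSE]
    if (nrow(reps) == 0 || nrow(expressed) == 0)
        return(data.frame(protein_id = character(), sample = character(),
                          nsaf = numeric(), cluster_id = character(),
                          aa_identity = numeric()))
    rep_seq <- genes$aa_sequence[match(reps$representative_gene,
                                       genes$gene_id)]
    out <- lapply(seq_len(nrow(expressed)), function(i) {
        ids <- vapply(rep_seq, function(s)
            alignmentIdentity(expressed$aa_sequence[i], s, type = "aa",
                              denominator = config@identityDenominator),
            numeric(1))
        best <- which.max(ids)
        if (ids[best] < config@aaLinkIdentity) return(NULL)
        data.frame(protein_id = expressed$protein_id[i],
                   sample = expressed$sample[i],
                   nsaf = expressed$nsaf[i],
                   cluster_id = reps$cluster_id[best],
                   aa_identity = ids[best],
                   stringsAsFactors = FALSE)
    })
    out <- Filter(Negate(is.null), out)
    if (length(out) == 0)
        return(data.frame(protein_id = character(), sample = character(),
                          nsaf = numeric(), cluster_id = character(),
                          aa_identity = numeric()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
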