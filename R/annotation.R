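## Two-tier annotation filtering: HMM domain hits are filtered for model
## coverage, tiered e-values and overlapping annotations; CAZyme hits are
## then confirmed by a same-family similarity hit before any locus calling.

SUSD_MODELS <- c("PF07980", "PF12741", "PF14322", "PF12771")
SUSC_MODEL <- "TIGR04056"
SULFATASE_MODEL <- "PF00884"
CAZY_FAMILY_RE <- "^(GH|PL|CE|GT|CBM)[0-9]+(_[0-9]+)?$"

#' Is a model identifier a CAZy family name?
#'
#' CAZy families are GH/PL/CE/GT/CBM followed by a family number and an
#' optional subfamily suffix (e.g. \code{GH5_46}).
#'
#' @param model_id character vector of model identifiers.
#' @return logical vector.
#' @export
isCazyFamily <- function(model_id) grepl(CAZY_FAMILY_RE, model_id)

# Strip a subfamily suffix: GH5_46 -> GH5.
baseFamily <- function(family) sub("_[0-9]+$", "", family)

# Family comparison at subfamily level when both sides carry a subfamily,
# else at base-family level (CAZy similarity subjects are often listed at
# family level only).
sameFamily <- function(a, b) {
    both_sub <- grepl("_", a) & grepl("_", b)
    ifelse(both_sub, a == b, baseFamily(a) == baseFamily(b))
}

checkHitColumns <- function(hits, cols, what) {
    missing <- setdiff(cols, names(hits))
    if (length(missing))
        stop(what, " is missing column(s): ", paste(missing, collapse = ", "))
}

#' Filter HMM domain hits
#'
#' Applies the dbCAN-parser-style filter: a hit is retained when it covers
#' at least \code{minCoverage} of the HMM model and its independent e-value
#' passes the tier for its alignment length (\code{evalueLong} for
#' alignments longer than \code{shortAliLen} residues, \code{evalueShort}
#' otherwise). Among hits on the same gene whose aligned query regions
#' overlap by more than half of the shorter region, only the hit with the
#' lowest i-e-value is kept (ties: higher bitscore, then lexicographically
#' smaller model id).
#'
#' @param hits data.frame with columns \code{gene_id}, \code{model_id},
#'   \code{model_length}, \code{ali_from}, \code{ali_to} (model
#'   coordinates), \code{i_evalue}, \code{bitscore}; optional
#'   \code{qry_from}/\code{qry_to} (query coordinates, used for overlap
#'   resolution; the model coordinates are used when absent).
#' @param genes optional gene table; when given, hits referencing unknown
#'   genes are rejected with an error.
#' @param config a \code{\link{pulConfig}} object.
#' @return the retained rows of \code{hits}.
#' @examples
#' hits <- data.frame(gene_id = "g1", model_id = "GH16",
#'                    model_length = 300, ali_from = 10, ali_to = 250,
#'                    i_evalue = 1e-30, bitscore = 200)
#' filterDomainHits(hits)
#' @export
filterDomainHits <- function(hits, genes = NULL, config = pulConfig()) {
    checkHitColumns(hits, c("gene_id", "model_id", "model_length",
                            "ali_from", "ali_to", "i_evalue", "bitscore"),
                    "domain hit table")
    if (nrow(hits) == 0) return(hits)
    if (!is.null(genes)) {
        unknown <- setdiff(hits$gene_id, genes$gene_id)
        if (length(unknown))
            stop("domain hits reference unknown gene(s): ",
                 paste(head(unknown, 5), collapse = ", "))
    }
    if (any(hits$i_evalue < 0)) stop("negative i_evalue in domain hits")
    ali_len <- hits$ali_to - hits$ali_from + 1
    coverage <- ali_len / hits$model_length
    if (any(coverage < 0 | coverage > 1))
        stop("malformed hit: model coverage outside [0, 1]")
    emax <- ifelse(ali_len > config@shortAliLen,
                   config@evalueLong, config@evalueShort)
    keep <- coverage >= config@minCoverage & hits$i_evalue <= emax
    hits <- hits[keep, , drop = FALSE]
    if (nrow(hits) <= 1) return(hits)

    qf <- if ("qry_from" %in% names(hits)) hits$qry_from else hits$ali_from
    qt <- if ("qry_to" %in% names(hits)) hits$qry_to else hits$ali_to
    keep_idx <- unlist(lapply(split(seq_len(nrow(hits)), hits$gene_id),
                              function(idx) {
        if (length(idx) == 1) return(idx)
        ord <- idx[order(hits$i_evalue[idx], -hits$bitscore[idx],
                         hits$model_id[idx])]
        accepted <- integer(0)
        for (i in ord) {
            clash <- FALSE
            for (j in accepted) {
                ov <- min(qt[i], qt[j]) - max(qf[i], qf[j]) + 1
                shorter <- min(qt[i] - qf[i], qt[j] - qf[j]) + 1
                if (ov > shorter / 2) { clash <- TRUE; break }
            }
            if (!clash) accepted <- c(accepted, i)
        }
        accepted
    }))
    hits[sort(keep_idx), , drop = FALSE]
}

#' Confirm CAZyme annotations with similarity evidence
#'
#' A (gene, family) annotation from the filtered HMM hits is confirmed only
#' when the gene also has a similarity hit to a protein of the same CAZy
#' family at \code{>= minIdentity} percent identity, \code{>= minQcov}
#' query coverage and e-value \code{<= maxEvalue}. Families are compared at
#' subfamily level when both sides carry a subfamily, else at family level.
#' Only confirmed annotations take part in locus calling.
#'
#' @param filteredHits output of \code{\link{filterDomainHits}}.
#' @param simHits data.frame with columns \code{query_gene_id},
#'   \code{subject_family}, \code{pct_identity}, \code{query_coverage},
#'   \code{evalue}.
#' @param config a \code{\link{pulConfig}} object.
#' @return data.frame with columns \code{gene_id}, \code{family} (unique,
#'   sorted).
#' @export
confirmCazymes <- function(filteredHits, simHits, config = pulConfig()) {
    checkHitColumns(simHits, c("query_gene_id", "subject_family",
                               "pct_identity", "query_coverage", "evalue"),
                    "similarity hit table")
    if (any(simHits$pct_identity < 0 | simHits$pct_identity > 100))
        stop("pct_identity outside [0, 100]")
    if (any(simHits$query_coverage < 0 | simHits$query_coverage > 1))
        stop("query_coverage outside [0, 1]")
    cazy <- filteredHits[isCazyFamily(filteredHits$model_id), , drop = FALSE]
    if (nrow(cazy) == 0)
        return(data.frame(gene_id = character(), family = character()))
    cand <- unique(data.frame(gene_id = cazy$gene_id,
                              family = cazy$model_id,
                              stringsAsFactors = FALSE))
    ok <- simHits$pct_identity >= config@minIdentity &
        simHits$query_coverage >= config@minQcov &
        simHits$evalue <= config@maxEvalue
    sim <- simHits[ok, , drop = FALSE]
    confirmed <- vapply(seq_len(nrow(cand)), function(i) {
        rows <- sim$query_gene_id == cand$gene_id[i]
        any(rows & sameFamily(cand$family[i], sim$subject_family))
    }, logical(1))
    out <- cand[confirmed, , drop = FALSE]
    out <- out[order(out$gene_id, out$family), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Assign per-gene roles
#'
#' Combines filtered domain hits and confirmed CAZyme families into one
#' role label per gene: \code{susD} from any of the four SusD Pfam models,
#' \code{susC} from TIGR04056, \code{sulfatase} from PF00884, and
#' \code{cazyme} from the confirmed families only. A gene whose confirmed
#' families are all glycosyltransferases (GT) and which carries no other
#' role is flagged \code{is_gt_only}.
#'
#' @param genes gene table with columns \code{contig_id}, \code{gene_index},
#'   \code{gene_id} (plus coordinates).
#' @param confirmed output of \code{\link{confirmCazymes}}.
#' @param filteredHits output of \code{\link{filterDomainHits}}.
#' @return the gene table with added columns \code{roles} (comma-joined
#'   tokens among susC, susD, sulfatase, cazyme), \code{families}
#'   (comma-joined confirmed CAZy families) and \code{is_gt_only}.
#' @export
assignRoles <- function(genes, confirmed, filteredHits) {
    fam_by_gene <- split(confirmed$family, confirmed$gene_id)
    roles <- vapply(genes$gene_id, function(g) {
        mods <- filteredHits$model_id[filteredHits$gene_id == g]
        r <- character(0)
        if (SUSC_MODEL %in% mods) r <- c(r, "susC")
        if (any(SUSD_MODELS %in% mods)) r <- c(r, "susD")
        if (SULFATASE_MODEL %in% mods) r <- c(r, "sulfatase")
        if (length(fam_by_gene[[g]])) r <- c(r, "cazyme")
        paste(r, collapse = ",")
    }, character(1), USE.NAMES = FALSE)
    fams <- vapply(genes$gene_id, function(g)
        paste(sort(fam_by_gene[[g]]), collapse = ","),
        character(1), USE.NAMES = FALSE)
    out <- genes
    out$roles <- roles
    out$families <- fams
    famlist <- strsplit(fams, ",", fixed = TRUE)
    out$is_gt_only <- vapply(seq_along(famlist), function(i) {
        f <- famlist[[i]]
        length(f) > 0 && all(grepl("^GT", f)) && roles[i] == "cazyme"
    }, logical(1))
    out
}

#' Run the full annotation stage
#'
#' Convenience wrapper: filter domain hits, confirm CAZymes, assign roles.
#'
#' @inheritParams filterDomainHits
#' @inheritParams confirmCazymes
#' @return annotated gene table (see \code{\link{assignRoles}}).
#' @export
annotateGenes <- function(genes, hits, simHits, config = pulConfig()) {
    filtered <- filterDomainHits(hits, genes = genes, config = config)
    confirmed <- confirmCazymes(filtered, simHits, config = config)
    assignRoles(genes, confirmed, filtered)
}
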