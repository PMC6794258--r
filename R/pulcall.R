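## Locus extraction: marker genes (sulfatases, confirmed CAZymes, SusC/D)
## are chained along each contig; chains with enough markers that are not
## exclusively glycosyltransferases become candidates, and candidates are
## retained when they carry a susC/susD-like gene and at least two
## degradative (GH/PL) CAZyme genes.

#' PULSet: called polysaccharide utilization loci
#'
#' Container for the loci called on a set of annotated contigs, the
#' annotated gene table they were called from, and the configuration used.
#'
#' @slot loci a \link[S4Vectors]{DataFrame} with one row per locus:
#'   \code{pul_id}, \code{contig_id}, \code{first_index}/\code{last_index}
#'   (gene-index span), \code{n_markers}, \code{marker_gene_ids},
#'   \code{families} (confirmed CAZy families of the marker genes, with
#'   multiplicity), \code{n_sulfatase}, \code{degradative_count},
#'   \code{n_susC}, \code{n_susD}, \code{susCD_pairs} (adjacent susC/susD
#'   index pairs, formatted \code{"i-j"}), \code{touches_edge}, and after
#'   \code{\link{classifySubstrates}} also \code{substrate}, \code{variant},
#'   \code{matched_evidence} and \code{multi_match}.
#' @slot genes the annotated gene table (see \code{\link{assignRoles}}).
#' @slot config the \linkS4class{PULConfig} used.
#' @export
setClass("PULSet", representation(
    loci = "DataFrame",
    genes = "data.frame",
    config = "PULConfig"
))

setValidity("PULSet", function(object) {
    lo <- object@loci
    need <- c("pul_id", "contig_id", "first_index", "last_index",
              "n_markers", "degradative_count", "n_susC", "n_susD")
    missing <- setdiff(need, colnames(lo))
    if (length(missing))
        return(paste("loci lacks column(s):", paste(missing, collapse = ", ")))
    if (nrow(lo) == 0) return(TRUE)
    cfg <- object@config
    if (any(lo$last_index < lo$first_index))
        return("locus span reversed")
    if (any(lo$n_markers < cfg@minMarkers))
        return("locus with fewer markers than minMarkers")
    if (any(lo$n_susC + lo$n_susD < cfg@minSusCD))
        return("locus without a susC/susD-like gene")
    if (any(lo$degradative_count < cfg@minDegradative))
        return("locus with fewer than minDegradative GH/PL genes")
    TRUE
})

#' @describeIn PULSet number of called loci.
#' @param x a \code{PULSet}.
#' @export
setMethod("length", "PULSet", function(x) nrow(x@loci))

#' Extract the locus table
#'
#' @param x a \linkS4class{PULSet}.
#' @return the loci \link[S4Vectors]{DataFrame}.
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname loci
#' @export
setMethod("loci", "PULSet", function(x) x@loci)

#' @describeIn PULSet brief display.
#' @param object a \code{PULSet}.
#' @export
setMethod("show", "PULSet", function(object) {
    cat(sprintf("PULSet with %d loci on %d contigs (%d genes annotated)\n",
                nrow(object@loci), length(unique(object@genes$contig_id)),
                nrow(object@genes)))
    if (nrow(object@loci) > 0 && "substrate" %in% colnames(object@loci)) {
        tab <- table(object@loci$substrate)
        cat("  substrates:",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    }
})

roleList <- function(genes) strsplit(genes$roles, ",", fixed = TRUE)
famList <- function(genes) strsplit(genes$families, ",", fixed = TRUE)

#' Chain marker genes on one contig
#'
#' Marker genes (any nonempty role) are chained transitively whenever the
#' number of genes strictly between two consecutive markers is less than
#' \code{maxGap}. Each maximal chain with at least \code{minMarkers}
#' markers is a candidate locus, unless its markers are exclusively
#' GT-only genes.
#'
#' @param genes annotated gene table for a single contig, ordered by
#'   \code{gene_index} (consecutive).
#' @param config a \code{\link{pulConfig}}.
#' @return list of candidates, each a list with \code{contig_id},
#'   \code{first_index}, \code{last_index} and \code{marker_rows} (row
#'   indices into \code{genes}).
#' @export
chainMarkers <- function(genes, config = pulConfig()) {
    if (length(unique(genes$contig_id)) > 1)
        stop("chainMarkers expects genes of a single contig")
    if (is.unsorted(genes$gene_index, strictly = TRUE))
        stop("gene table not ordered by gene_index")
    if (nrow(genes) > 1 && any(diff(genes$gene_index) != 1))
        stop("gene_index not consecutive")
    marker_rows <- which(genes$roles != "")
    if (length(marker_rows) == 0) return(list())
    idx <- genes$gene_index[marker_rows]
    ## break the chain where >= maxGap genes lie strictly between markers
    breaks <- which(diff(idx) - 1 >= config@maxGap)
    grp <- cumsum(c(1, seq_along(idx)[-1] %in% (breaks + 1)))
    out <- list()
    for (g in unique(grp)) {
        rows <- marker_rows[grp == g]
        if (length(rows) < config@minMarkers) next
        if (all(genes$is_gt_only[rows])) next
        out[[length(out) + 1]] <- list(
            contig_id = genes$contig_id[1],
            first_index = genes$gene_index[rows[1]],
            last_index = genes$gene_index[rows[length(rows)]],
            marker_rows = rows)
    }
    out
}

#' Apply the locus retention filter
#'
#' A candidate chain becomes a PUL when it contains at least one gene with
#' a susC or susD role and at least two genes carrying a confirmed
#' degradative CAZyme family (GH or PL; CE, GT and CBM do not count).
#' Adjacent susC/susD gene pairs (either order) are recorded.
#'
#' @param candidates output of \code{\link{chainMarkers}}.
#' @param genes the contig gene table the candidates refer to.
#' @param config a \code{\link{pulConfig}}.
#' @return list of retained loci with added fields \code{marker_gene_ids},
#'   \code{families}, \code{n_sulfatase}, \code{degradative_count},
#'   \code{n_susC}, \code{n_susD}, \code{susCD_pairs}, \code{touches_edge}.
#' @export
filterCandidates <- function(candidates, genes, config = pulConfig()) {
    roles <- roleList(genes)
    fams <- famList(genes)
    contig_lo <- min(genes$gene_index)
    contig_hi <- max(genes$gene_index)
    out <- list()
    for (cand in candidates) {
        rows <- cand$marker_rows
        has_role <- function(role) vapply(roles[rows], function(r)
            role %in% r, logical(1))
        is_susC <- has_role("susC")
        is_susD <- has_role("susD")
        degradative <- vapply(fams[rows], function(f)
            any(grepl("^(GH|PL)[0-9]", f)), logical(1))
        if (sum(is_susC) + sum(is_susD) < config@minSusCD) next
        if (sum(degradative) < config@minDegradative) next
        idx <- genes$gene_index[rows]
        pairs <- character(0)
        for (i in seq_along(rows)[-1]) {
            if (idx[i] - idx[i - 1] == 1 &&
                ((is_susC[i - 1] && is_susD[i]) ||
                 (is_susD[i - 1] && is_susC[i])))
                pairs <- c(pairs, paste0(idx[i - 1], "-", idx[i]))
        }
        cand$marker_gene_ids <- genes$gene_id[rows]
        cand$families <- unlist(fams[rows])
        cand$n_sulfatase <- sum(has_role("sulfatase"))
        cand$degradative_count <- sum(degradative)
        cand$n_susC <- sum(is_susC)
        cand$n_susD <- sum(is_susD)
        cand$susCD_pairs <- pairs
        cand$touches_edge <- cand$first_index == contig_lo ||
            cand$last_index == contig_hi
        out[[length(out) + 1]] <- cand
    }
    out
}

#' Call PULs on annotated contigs
#'
#' Runs \code{\link{chainMarkers}} and \code{\link{filterCandidates}} per
#' contig and collects the result in a \linkS4class{PULSet}. Loci are
#' reported in contig order, then by position.
#'
#' @param annotated annotated gene table over any number of contigs (see
#'   \code{\link{assignRoles}}).
#' @param config a \code{\link{pulConfig}}.
#' @return a \linkS4class{PULSet}.
#' @examples
#' genes <- data.frame(
#'   contig_id = "c1", gene_index = 0:3,
#'   gene_id = paste0("g", 1:4), start = (0:3) * 1000 + 1,
#'   end = (0:3) * 1000 + 900, strand = "+", aa_length = 300,
#'   roles = c("susC", "susD", "cazyme", "cazyme"),
#'   families = c("", "", "GH16", "GH3"),
#'   is_gt_only = FALSE)
#' callPuls(genes)
#' @export
callPuls <- function(annotated, config = pulConfig()) {
    found <- list()
    for (contig in unique(annotated$contig_id)) {
        sub <- annotated[annotated$contig_id == contig, , drop = FALSE]
        sub <- sub[order(sub$gene_index), , drop = FALSE]
        cands <- chainMarkers(sub, config)
        found <- c(found, filterCandidates(cands, sub, config))
    }
    if (length(found) == 0) {
        loci <- S4Vectors::DataFrame(
            pul_id = character(), contig_id = character(),
            first_index = integer(), last_index = integer(),
            n_markers = integer(),
            marker_gene_ids = IRanges::CharacterList(),
            families = IRanges::CharacterList(),
            n_sulfatase = integer(), degradative_count = integer(),
            n_susC = integer(), n_susD = integer(),
            susCD_pairs = IRanges::CharacterList(),
            touches_edge = logical())
    } else {
        loci <- S4Vectors::DataFrame(
            pul_id = sprintf("pul_%03d", seq_along(found)),
            contig_id = vapply(found, `[[`, character(1), "contig_id"),
            first_index = vapply(found, `[[`, numeric(1), "first_index"),
            last_index = vapply(found, `[[`, numeric(1), "last_index"),
            n_markers = vapply(found, function(x)
                length(x$marker_rows), integer(1)),
            marker_gene_ids = IRanges::CharacterList(
                lapply(found, `[[`, "marker_gene_ids")),
            families = IRanges::CharacterList(
                lapply(found, function(x) x$families[x$families != ""])),
            n_sulfatase = vapply(found, `[[`, numeric(1), "n_sulfatase"),
            degradative_count = vapply(found, `[[`, numeric(1),
                                       "degradative_count"),
            n_susC = vapply(found, `[[`, numeric(1), "n_susC"),
            n_susD = vapply(found, `[[`, numeric(1), "n_susD"),
            susCD_pairs = IRanges::CharacterList(
                lapply(found, `[[`, "susCD_pairs")),
            touches_edge = vapply(found, `[[`, logical(1), "touches_edge"))
    }
    new("PULSet", loci = loci, genes = annotated, config = config)
}
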