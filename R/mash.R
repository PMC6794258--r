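## MinHash sketching and Mash distance for approximate-species clustering
## of MAGs. Sketches are bottom-s sets of 53-bit hashes of canonical
## k-mers; the distance D = -(1/k) ln(2j/(1+j)) uses the union-sketch
## Jaccard estimate j and correlates with 1 - ANI, so that D <= 0.05
## approximates >= 95% ANI (the usual same-species threshold).

#' MashSketch: bottom-s MinHash sketch of a MAG
#'
#' @slot magId genome/MAG identifier.
#' @slot k k-mer size.
#' @slot sketchSize maximum number of retained hashes (s).
#' @slot seed hash seed; sketches are only comparable at equal k,
#'   sketchSize and seed.
#' @slot hashes sorted ascending hash values (53-bit integers stored as
#'   doubles).
#' @slot nSkipped number of k-mer windows skipped for non-ACGT characters.
#' @export
setClass("MashSketch", representation(
    magId = "character",
    k = "numeric",
    sketchSize = "numeric",
    seed = "numeric",
    hashes = "numeric",
    nSkipped = "numeric"
))

setValidity("MashSketch", function(object) {
    if (length(object@hashes) > object@sketchSize)
        return("more hashes than sketchSize")
    if (is.unsorted(object@hashes, strictly = TRUE))
        return("hashes must be sorted ascending and distinct")
    if (object@k < 1) return("k must be >= 1")
    TRUE
})

#' @describeIn MashSketch brief display.
#' @param object a \code{MashSketch}.
#' @export
setMethod("show", "MashSketch", function(object) {
    cat(sprintf("MashSketch '%s': k=%d s=%d seed=%s, %d hashes (%d windows skipped)\n",
                object@magId, as.integer(object@k),
                as.integer(object@sketchSize), format(object@seed),
                length(object@hashes), as.integer(object@nSkipped)))
})

#' Sketch a nucleotide sequence
#'
#' Builds the bottom-\code{s} MinHash sketch over canonical k-mers (the
#' lexicographic minimum of each k-mer and its reverse complement).
#' Duplicate k-mers are hashed once; windows containing non-ACGT
#' characters are skipped and counted.
#'
#' @param sequence a single \link[Biostrings]{DNAString}, a length-1
#'   \code{DNAStringSet} (multi-contig MAGs: pass each contig separately or
#'   concatenate), or a character string.
#' @param magId identifier stored in the sketch.
#' @param k k-mer size (default 21).
#' @param s sketch size (default 1000).
#' @param seed hash seed.
#' @return a \linkS4class{MashSketch}.
#' @examples
#' sk <- sketchSequence(makeGenome(5000, seed = 1), magId = "mag1")
#' sk
#' @export
sketchSequence <- function(sequence, magId = "", k = 21, s = 1000,
                           seed = 42) {
    if (methods::is(sequence, "DNAStringSet")) {
        if (length(sequence) != 1)
            stop("pass one sequence at a time (or concatenate contigs)")
        sequence <- sequence[[1]]
    }
    seq_chr <- as.character(sequence)
    if (nchar(seq_chr) < k) stop("sequence shorter than k")
    res <- cpp_sketch(seq_chr, as.integer(k), as.integer(s), as.numeric(seed))
    new("MashSketch", magId = as.character(magId), k = k, sketchSize = s,
        seed = seed, hashes = res$hashes, nSkipped = res$n_skipped)
}

#' Union-sketch Jaccard estimate
#'
#' The fraction of shared hashes among the s smallest distinct hashes of
#' the merged sketches; the estimator behind \code{\link{mashDistance}}.
#'
#' @param a,b \linkS4class{MashSketch} objects with equal k, sketch size
#'   and seed.
#' @return estimated Jaccard index in [0, 1].
#' @export
sketchJaccard <- function(a, b) {
    if (a@k != b@k || a@sketchSize != b@sketchSize || a@seed != b@seed)
        stop("sketches built with different k, sketch size or seed")
    uj <- cpp_union_jaccard(a@hashes, b@hashes, as.integer(a@sketchSize))
    if (uj$taken == 0) stop("empty sketches")
    uj$shared / uj$taken
}

#' Mash distance between two sketches
#'
#' Estimates the Jaccard index j as the fraction of shared hashes among
#' the s smallest distinct hashes of the merged sketches, then applies
#' D = -(1/k) * ln(2j / (1 + j)). D is defined as 1 when j = 0.
#'
#' @param a,b \linkS4class{MashSketch} objects with equal k, sketch size
#'   and seed.
#' @return distance in [0, 1].
#' @examples
#' g <- makeGenome(20000, seed = 7)
#' m <- mutateGenome(g, 0.03, seed = 8)
#' mashDistance(sketchSequence(g), sketchSequence(m))
#' @export
mashDistance <- function(a, b) {
    if (a@k != b@k || a@sketchSize != b@sketchSize || a@seed != b@seed)
        stop("sketches built with different k, sketch size or seed")
    uj <- cpp_union_jaccard(a@hashes, b@hashes, as.integer(a@sketchSize))
    if (uj$taken == 0) stop("empty sketches")
    j <- uj$shared / uj$taken
    if (j == 0) return(1)
    min(1, max(0, -(1 / a@k) * log(2 * j / (1 + j))))
}

#' All-pairs Mash distance matrix
#'
#' @param sketches list of \linkS4class{MashSketch} objects.
#' @return symmetric matrix with zero diagonal, dimnames = MAG ids.
#' @export
mashDistanceMatrix <- function(sketches) {
    n <- length(sketches)
    ids <- vapply(sketches, function(x) x@magId, character(1))
    if (anyDuplicated(ids)) stop("duplicate MAG ids among sketches")
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    if (n < 2) return(D)
    for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
            D[i, j] <- D[j, i] <- mashDistance(sketches[[i]], sketches[[j]])
        }
    }
    D
}

#' Exact canonical k-mer Jaccard index
#'
#' Brute-force enumeration of all distinct canonical k-mers of two
#' sequences; intended as an oracle for the sketch estimator on short
#' sequences.
#'
#' @param seqA,seqB sequences (character or \code{DNAString}).
#' @param k k-mer size.
#' @return exact Jaccard index of the two canonical k-mer sets.
#' @export
exactCanonicalJaccard <- function(seqA, seqB, k = 21) {
    canon <- function(s) {
        s <- Biostrings::DNAString(as.character(s))
        n <- length(s)
        if (n < k) stop("sequence shorter than k")
        kmers <- substring(as.character(s), seq_len(n - k + 1),
                           seq_len(n - k + 1) + k - 1)
        keep <- !grepl("[^ACGT]", kmers)
        kmers <- kmers[keep]
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(kmers)))
        unique(pmin(kmers, rc))
    }
    a <- canon(seqA)
    b <- canon(seqB)
    length(intersect(a, b)) / length(union(a, b))
}

#' Cluster MAGs into approximate species
#'
#' Single-linkage clustering: MAGs are connected whenever their Mash
#' distance is at most \code{threshold}; clusters are the connected
#' components (matching the network depiction of approximate-species
#' clusters). Cluster ids \code{mc_N} are assigned in order of each
#' cluster's lexicographically smallest member, so the labelling is
#' invariant to input order.
#'
#' @param D symmetric distance matrix with zero diagonal (as from
#'   \code{\link{mashDistanceMatrix}}).
#' @param threshold species-level distance cutoff (default 0.05).
#' @param linkage \code{"single"} (connected components; default) or
#'   \code{"complete"}.
#' @return data.frame with columns \code{mag_id}, \code{cluster_id}.
#' @export
clusterMags <- function(D, threshold = 0.05, linkage = c("single",
                                                         "complete")) {
    linkage <- match.arg(linkage)
    if (!isSymmetric(unname(D), tol = 1e-12))
        stop("distance matrix must be symmetric")
    if (any(diag(D) != 0)) stop("distance matrix must have zero diagonal")
    ids <- rownames(D)
    if (is.null(ids)) stop("distance matrix needs MAG ids as dimnames")
    if (linkage == "single") {
        adj <- D <= threshold
        g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                                 diag = FALSE)
        comp <- igraph::components(g)$membership
    } else {
        hc <- stats::hclust(stats::as.dist(D), method = "complete")
        comp <- stats::cutree(hc, h = threshold)
    }
    ## deterministic ids by smallest member
    smallest <- tapply(ids, comp, min)
    rank <- match(names(sort(smallest)), names(smallest))
    relabel <- setNames(match(seq_along(smallest), rank), names(smallest))
    data.frame(mag_id = ids,
               cluster_id = sprintf("mc_%d", relabel[as.character(comp)]),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply MAG-quality gates to clusters
#'
#' A multi-MAG cluster is retained when at least two members reach
#' \code{minCompleteness}; a singleton is excluded only when its
#' completeness is at most \code{minCompleteness} \emph{and} its
#' contamination is at least \code{maxContamination}.
#'
#' @param clusters data.frame from \code{\link{clusterMags}}.
#' @param qualities data.frame with columns \code{mag_id},
#'   \code{completeness}, \code{contamination} (percent).
#' @param config a \code{\link{pulConfig}}.
#' @return per-cluster data.frame: \code{cluster_id}, \code{n_mags},
#'   \code{retained}.
#' @export
qualityFilter <- function(clusters, qualities, config = pulConfig()) {
    missing <- setdiff(clusters$mag_id, qualities$mag_id)
    if (length(missing))
        stop("no quality record for MAG(s): ",
             paste(head(missing, 5), collapse = ", "))
    if (any(qualities$completeness < 0 | qualities$completeness > 100))
        stop("completeness outside [0, 100]")
    if (any(qualities$contamination < 0))
        stop("negative contamination")
    q <- qualities[match(clusters$mag_id, qualities$mag_id), ]
    per <- split(seq_len(nrow(clusters)), clusters$cluster_id)
    out <- data.frame(cluster_id = names(per),
                      n_mags = lengths(per),
                      retained = NA,
                      row.names = NULL, stringsAsFactors = FALSE)
    out$retained <- vapply(per, function(idx) {
        comp <- q$completeness[idx]
        cont <- q$contamination[idx]
        if (length(idx) >= 2) {
            sum(comp >= config@minCompleteness) >= 2
        } else {
            !(comp <= config@minCompleteness &&
              cont >= config@maxContamination)
        }
    }, logical(1))
    out[order(out$cluster_id), , drop = FALSE]
}

#' Pick representative MAGs for a cluster
#'
#' The (up to) two members with the highest completeness; ties are broken
#' by lower contamination, then lexicographic MAG id. A singleton yields
#' one representative.
#'
#' @param mag_ids members of one cluster.
#' @param qualities quality table (see \code{\link{qualityFilter}}).
#' @return character vector of 1 or 2 MAG ids, best first.
#' @export
pickRepresentatives <- function(mag_ids, qualities) {
    q <- qualities[match(mag_ids, qualities$mag_id), ]
    if (any(is.na(q$mag_id)))
        stop("no quality record for MAG(s): ",
             paste(mag_ids[is.na(q$mag_id)], collapse = ", "))
    ord <- order(-q$completeness, q$contamination, q$mag_id)
    q$mag_id[ord][seq_len(min(2, length(mag_ids)))]
}

#' Flag an abundant cluster
#'
#' TRUE when the per-sample RPKM values exceed \code{rpkmSingle} in any
#' single sample or \code{rpkmTotal} summed over all samples (strict
#' inequalities). An empty vector is treated as all-zero.
#'
#' @param rpkm_values per-sample RPKM values for one cluster.
#' @param config a \code{\link{pulConfig}}.
#' @return logical.
#' @examples
#' flagAbundant(c(6, 0, 0))   # TRUE: one sample above 5 RPKM
#' flagAbundant(rep(1, 38))   # FALSE: sum equals, does not exceed, 38
#' @export
flagAbundant <- function(rpkm_values, config = pulConfig()) {
    if (length(rpkm_values) == 0) return(FALSE)
    if (any(rpkm_values < 0)) stop("negative RPKM value")
    max(rpkm_values) > config@rpkmSingle ||
        sum(rpkm_values) > config@rpkmTotal
}

#' Build the full Mash-cluster table
#'
#' Convenience wrapper combining clustering, quality gates, representative
#' picking and abundance flags into one table mirroring the usual
#' supplementary-table layout.
#'
#' @param D distance matrix.
#' @param qualities quality table.
#' @param rpkm optional matrix of per-MAG, per-sample RPKM (rows = MAG
#'   ids); cluster abundance is the mean over representatives.
#' @param config a \code{\link{pulConfig}}.
#' @return data.frame with one row per MAG: \code{cluster_id},
#'   \code{mag_id}, \code{completeness}, \code{contamination},
#'   \code{retained}, \code{representative}, \code{abundant}.
#' @export
mashClusterTable <- function(D, qualities, rpkm = NULL,
                             config = pulConfig()) {
    clusters <- clusterMags(D, threshold = config@mashThreshold)
    gates <- qualityFilter(clusters, qualities, config)
    tab <- merge(clusters, qualities, by = "mag_id", sort = FALSE)
    tab <- merge(tab, gates[, c("cluster_id", "retained")], by = "cluster_id",
                 sort = FALSE)
    tab$representative <- FALSE
    tab$abundant <- NA
    for (cl in unique(tab$cluster_id)) {
        rows <- tab$cluster_id == cl
        if (!tab$retained[rows][1]) next
        reps <- pickRepresentatives(tab$mag_id[rows], qualities)
        tab$representative[rows] <- tab$mag_id[rows] %in% reps
        if (!is.null(rpkm)) {
            vals <- colMeans(rpkm[reps, , drop = FALSE])
            tab$abundant[rows] <- flagAbundant(vals, config)
        }
    }
    tab <- tab[order(tab$cluster_id, tab$mag_id), ]
    rownames(tab) <- NULL
    tab
}
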