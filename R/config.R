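#' Pipeline configuration
#'
#' Holds every tunable threshold of the pipeline in one validated object.
#' Defaults follow the published workflow: the dbCAN-style two-tier
#' annotation filter (30% model coverage; e-value 1e-5 for alignments
#' longer than 80 aa, else 1e-3; similarity confirmation at >=30% identity,
#' >=40% query coverage, e-value <=1e-20), locus chaining with markers
#' fewer than 10 genes apart and at least 3 markers, retention with >=1
#' susC/susD gene and >=2 GH/PL genes, Mash sketching at k = 21 with
#' sketch size 1000 and species clustering at distance <=0.05, MAG quality
#' gates at 70% completeness / 10% contamination, abundance flags at 5 RPKM
#' (single sample) or 38 RPKM (summed), SusC/D dereplication at >=95%
#' nucleotide identity, representative selection at 4 (or 3 + proteome
#' support) metagenomes, and expressed-protein linking at >=90% amino acid
#' identity.
#'
#' @slot minCoverage minimum aligned fraction of the HMM model.
#' @slot evalueLong,evalueShort independent e-value ceilings for alignments
#'   longer than (resp. at most) \code{shortAliLen} residues.
#' @slot shortAliLen alignment-length cutoff (residues) between the two
#'   e-value tiers.
#' @slot minIdentity,minQcov,maxEvalue similarity-confirmation thresholds
#'   (percent identity, query-coverage fraction, e-value).
#' @slot maxGap chaining breaks when >= this many genes separate two
#'   consecutive marker genes.
#' @slot minMarkers minimum marker genes per candidate locus.
#' @slot minSusCD minimum susC/susD-like genes per retained locus.
#' @slot minDegradative minimum genes with a confirmed GH or PL family.
#' @slot kmerSize,sketchSize,hashSeed MinHash sketch parameters.
#' @slot mashThreshold species-level Mash distance cutoff.
#' @slot minCompleteness,maxContamination MAG quality gates (percent).
#' @slot rpkmSingle,rpkmTotal abundance flags (RPKM exceeded in one sample,
#'   or summed over all samples).
#' @slot ntClusterIdentity SusC/D dereplication identity (percent,
#'   nucleotide).
#' @slot aaLinkIdentity expressed-protein link identity (percent, amino
#'   acid).
#' @slot minMetagenomes,altMetagenomes representative-selection criteria
#'   (metagenome counts; the lower count requires proteome support).
#' @slot identityDenominator "alignment" (gaps count against identity) or
#'   "shorter" (denominator = shorter sequence length).
#' @slot relaxedLaminarinC enable the relaxed GH5_46 + GH30_1 beta-glucan
#'   rule for loci lacking a GH16.
#' @export
setClass("PULConfig", representation(
    minCoverage = "numeric",
    evalueLong = "numeric",
    evalueShort = "numeric",
    shortAliLen = "numeric",
    minIdentity = "numeric",
    minQcov = "numeric",
    maxEvalue = "numeric",
    maxGap = "numeric",
    minMarkers = "numeric",
    minSusCD = "numeric",
    minDegradative = "numeric",
    kmerSize = "numeric",
    sketchSize = "numeric",
    hashSeed = "numeric",
    mashThreshold = "numeric",
    minCompleteness = "numeric",
    maxContamination = "numeric",
    rpkmSingle = "numeric",
    rpkmTotal = "numeric",
    ntClusterIdentity = "numeric",
    aaLinkIdentity = "numeric",
    minMetagenomes = "numeric",
    altMetagenomes = "numeric",
    identityDenominator = "character",
    relaxedLaminarinC = "logical"
), prototype(
    minCoverage = 0.30,
    evalueLong = 1e-5,
    evalueShort = 1e-3,
    shortAliLen = 80,
    minIdentity = 30,
    minQcov = 0.40,
    maxEvalue = 1e-20,
    maxGap = 10,
    minMarkers = 3,
    minSusCD = 1,
    minDegradative = 2,
    kmerSize = 21,
    sketchSize = 1000,
    hashSeed = 42,
    mashThreshold = 0.05,
    minCompleteness = 70,
    maxContamination = 10,
    rpkmSingle = 5,
    rpkmTotal = 38,
    ntClusterIdentity = 95,
    aaLinkIdentity = 90,
    minMetagenomes = 4,
    altMetagenomes = 3,
    identityDenominator = "alignment",
    relaxedLaminarinC = FALSE
))

setValidity("PULConfig", function(object) {
    msgs <- character()
    chk <- function(ok, msg) if (!isTRUE(ok)) msgs <<- c(msgs, msg)
    chk(object@minCoverage >= 0 && object@minCoverage <= 1,
        "minCoverage must be in [0, 1]")
    chk(object@minQcov >= 0 && object@minQcov <= 1,
        "minQcov must be in [0, 1]")
    chk(object@minIdentity >= 0 && object@minIdentity <= 100,
        "minIdentity must be in [0, 100]")
    chk(all(c(object@evalueLong, object@evalueShort, object@maxEvalue) >= 0),
        "e-value thresholds must be >= 0")
    chk(object@maxGap >= 1, "maxGap must be >= 1")
    chk(object@minMarkers >= 1, "minMarkers must be >= 1")
    chk(object@kmerSize >= 1 && object@kmerSize <= 31,
        "kmerSize must be in [1, 31]")
    chk(object@sketchSize >= 1, "sketchSize must be >= 1")
    chk(object@mashThreshold >= 0 && object@mashThreshold <= 1,
        "mashThreshold must be in [0, 1]")
    chk(object@minCompleteness >= 0 && object@minCompleteness <= 100,
        "minCompleteness must be in [0, 100]")
    chk(object@ntClusterIdentity > 0 && object@ntClusterIdentity <= 100,
        "ntClusterIdentity must be in (0, 100]")
    chk(object@aaLinkIdentity > 0 && object@aaLinkIdentity <= 100,
        "aaLinkIdentity must be in (0, 100]")
    chk(object@identityDenominator %in% c("alignment", "shorter"),
        "identityDenominator must be 'alignment' or 'shorter'")
    if (length(msgs)) msgs else TRUE
})

#' Create a pipeline configuration
#'
#' @param ... named overrides for any \linkS4class{PULConfig} slot.
#' @return a validated \linkS4class{PULConfig} object.
#' @examples
#' cfg <- pulConfig()
#' strict <- pulConfig(minIdentity = 50, maxGap = 5)
#' @export
pulConfig <- function(...) {
    args <- list(...)
    obj <- do.call(new, c(list(Class = "PULConfig"), args))
    validObject(obj)
    obj
}

#' @describeIn pulConfig display all thresholds.
#' @param object a \code{PULConfig}.
#' @export
setMethod("show", "PULConfig", function(object) {
    cat("PULConfig\n")
    for (sl in slotNames(object)) {
        cat(sprintf("  %-20s %s\n", sl,
                    paste(slot(object, sl), collapse = ", ")))
    }
})

# Serialize the configuration into a one-line provenance stamp used in
# output file headers.
configStamp <- function(config) {
    vals <- vapply(slotNames(config), function(sl)
        paste0(sl, "=", paste(slot(config, sl), collapse = "/")),
        character(1))
    paste(vals, collapse = " ")
}
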