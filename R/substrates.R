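## Rule-based substrate classification. The five substrate classes
## (beta-glucan/laminarin, alpha-glucan, alpha-mannose-rich, sulfated
## xylan, alginate) are recognised from the CAZyme-family composition of a
## locus via an editable, prioritised rule set distilled from the
## recurrent locus patterns: each rule states a required family multiset
## (plus optional and forbidden families); rules are evaluated most
## specific first and the first satisfied rule wins.

SUBSTRATE_LABELS <- c(beta_glucan = "beta-glucan/laminarin",
                      alpha_glucan = "alpha-glucan",
                      mannose = "alpha-mannose-rich",
                      xylan = "sulfated xylan",
                      alginate = "alginate")

#' Default substrate rule set
#'
#' Ten prioritised rules covering the five substrate classes and their
#' variants. \code{required} is a family multiset (family name to count;
#' the pseudo-family \code{sulfatase} counts sulfatase-role genes); a
#' family name without a subfamily suffix matches any subfamily.
#' \code{any_of} requires at least \code{k} of the listed families
#' (counting multiplicity). \code{forbidden} families must be absent.
#' \code{optional} families are reported as matched evidence but never
#' affect the decision. More-constrained rules carry smaller priority
#' numbers so that "first match" is well defined.
#'
#' @param relaxedLaminarinC also accept GH5_46 + GH30_1 loci lacking a
#'   GH16 as beta-glucan/laminarin (variant-C-like loci seen in some
#'   genomes).
#' @return list of rules, ordered by priority.
#' @export
defaultSubstrateRules <- function(relaxedLaminarinC = FALSE) {
    rule <- function(name, label, priority, required = NULL, any_of = NULL,
                     forbidden = character(0), optional = character(0)) {
        list(name = name, label = label, priority = priority,
             required = required, any_of = any_of, forbidden = forbidden,
             optional = optional)
    }
    rules <- list(
        rule("sulfated_xylan_2", SUBSTRATE_LABELS[["xylan"]], 1,
             required = c(GH30 = 1, GH10 = 1, GH43_1 = 1, sulfatase = 3),
             optional = c("PL9", "CBM22")),
        rule("mannose_sulfated", SUBSTRATE_LABELS[["mannose"]], 2,
             required = c(GH92 = 3, sulfatase = 2),
             optional = c("GH2", "GH3", "GH43_2")),
        rule("mannose_sulfatase_free", SUBSTRATE_LABELS[["mannose"]], 3,
             required = c(GH92 = 1, GH130 = 1, GH20 = 1, GH18 = 1),
             forbidden = "sulfatase",
             optional = c("CBM9", "GH3", "GH2", "CE2")),
        rule("sulfated_xylan_1", SUBSTRATE_LABELS[["xylan"]], 4,
             required = c(GH10 = 1, GH3 = 1, sulfatase = 2)),
        rule("beta_glucan_B", SUBSTRATE_LABELS[["beta_glucan"]], 5,
             required = c(GH16 = 1, GH30_1 = 1, GH17 = 1)),
        rule("beta_glucan_C", SUBSTRATE_LABELS[["beta_glucan"]], 6,
             required = c(GH5_46 = 1, GH16 = 1)),
        rule("beta_glucan_A", SUBSTRATE_LABELS[["beta_glucan"]], 7,
             required = c(GH16 = 1, GH3 = 1),
             optional = c("GH2", "GH30_1")),
        rule("alpha_glucan_complex", SUBSTRATE_LABELS[["alpha_glucan"]], 8,
             required = c(GH13 = 2),
             optional = c("GH65", "GH43_12", "sulfatase")),
        rule("alpha_glucan_simple", SUBSTRATE_LABELS[["alpha_glucan"]], 9,
             required = c(GH65 = 1, GH13 = 1), optional = "CBM48"),
        rule("alginate", SUBSTRATE_LABELS[["alginate"]], 10,
             any_of = list(families = c("PL6", "PL7", "PL17"), k = 2)))
    if (relaxedLaminarinC) {
        rules <- c(rules, list(
            rule("beta_glucan_C_relaxed", SUBSTRATE_LABELS[["beta_glucan"]],
                 11, required = c(GH5_46 = 1, GH30_1 = 1))))
    }
    rules[order(vapply(rules, `[[`, numeric(1), "priority"))]
}

validateRules <- function(rules) {
    prio <- vapply(rules, `[[`, numeric(1), "priority")
    if (anyDuplicated(prio))
        stop("substrate rule set has duplicate priorities")
    for (r in rules) {
        if (is.null(r$required) && is.null(r$any_of))
            stop("rule '", r$name, "' has no requirements")
    }
    invisible(TRUE)
}

# Count occurrences of a (possibly family-level) requirement in a family
# multiset; sulfatase counts come from the sulfatase-role gene count.
countFamily <- function(req, families, n_sulfatase) {
    if (req == "sulfatase") return(n_sulfatase)
    if (grepl("_", req)) sum(families == req)
    else sum(baseFamily(families) == req)
}

ruleMatches <- function(r, families, n_sulfatase) {
    if (!is.null(r$required)) {
        for (f in names(r$required)) {
            if (countFamily(f, families, n_sulfatase) < r$required[[f]])
                return(FALSE)
        }
    }
    if (!is.null(r$any_of)) {
        n <- sum(vapply(r$any_of$families, countFamily, numeric(1),
                        families = families, n_sulfatase = n_sulfatase))
        if (n < r$any_of$k) return(FALSE)
    }
    for (f in r$forbidden) {
        if (countFamily(f, families, n_sulfatase) > 0) return(FALSE)
    }
    TRUE
}

#' Classify one locus by its CAZyme family composition
#'
#' @param families character vector of confirmed CAZy families of the
#'   locus, with multiplicity (one entry per gene-family assignment).
#' @param n_sulfatase number of sulfatase-role genes in the locus.
#' @param rules rule set (default \code{\link{defaultSubstrateRules}}).
#' @return list with \code{label} (substrate class or \code{"unknown"}),
#'   \code{variant} (winning rule name or \code{NA}),
#'   \code{matched_evidence} (families/roles satisfying the winning rule,
#'   required plus present optional), and \code{n_matching} (how many
#'   rules matched in total; more than one is flagged by callers).
#' @examples
#' classifySubstrate(c("GH16", "GH3"), 0)
#' classifySubstrate(c("PL6", "PL17"), 0)
#' @export
classifySubstrate <- function(families, n_sulfatase = 0,
                              rules = defaultSubstrateRules()) {
    validateRules(rules)
    matches <- vapply(rules, ruleMatches, logical(1),
                      families = families, n_sulfatase = n_sulfatase)
    if (!any(matches)) {
        return(list(label = "unknown", variant = NA_character_,
                    matched_evidence = character(0),
                    n_matching = 0L))
    }
    win <- rules[[which(matches)[1]]]
    evidence <- character(0)
    pool <- c(names(win$required), win$any_of$families, win$optional)
    for (f in unique(pool)) {
        n <- countFamily(f, families, n_sulfatase)
        if (n > 0) evidence <- c(evidence, rep(f, n))
    }
    list(label = win$label, variant = win$name,
         matched_evidence = evidence, n_matching = sum(matches))
}

#' Classify every locus of a PULSet
#'
#' @param pulset a \linkS4class{PULSet}.
#' @param rules substrate rule set.
#' @return the \code{PULSet} with \code{substrate}, \code{variant},
#'   \code{matched_evidence} and \code{multi_match} columns added to its
#'   locus table.
#' @export
classifySubstrates <- function(pulset, rules = defaultSubstrateRules()) {
    lo <- pulset@loci
    n <- nrow(lo)
    calls <- lapply(seq_len(n), function(i)
        classifySubstrate(lo$families[[i]], lo$n_sulfatase[i], rules))
    lo$substrate <- if (n) vapply(calls, `[[`, character(1), "label")
                    else character(0)
    lo$variant <- if (n) vapply(calls, `[[`, character(1), "variant")
                  else character(0)
    lo$matched_evidence <- IRanges::CharacterList(
        lapply(calls, `[[`, "matched_evidence"))
    lo$multi_match <- if (n) vapply(calls, function(x)
        x$n_matching > 1, logical(1)) else logical(0)
    initialize(pulset, loci = lo)
}

#' Read / write a substrate rule set as YAML
#'
#' The rule set ships as data, not code: users can edit the YAML and
#' reload it.
#'
#' @param rules rule set to write.
#' @param path file path.
#' @return \code{readSubstrateRules} returns the rule list (ordered by
#'   priority); \code{writeSubstrateRules} returns \code{path} invisibly.
#' @export
writeSubstrateRules <- function(rules, path) {
    ser <- lapply(rules, function(r) {
        r$required <- as.list(r$required)
        if (!is.null(r$any_of)) r$any_of$families <- as.list(r$any_of$families)
        r
    })
    yaml::write_yaml(ser, path)
    invisible(path)
}

#' @rdname writeSubstrateRules
#' @export
readSubstrateRules <- function(path) {
    raw <- yaml::read_yaml(path)
    rules <- lapply(raw, function(r) {
        if (!is.null(r$required)) r$required <- unlist(r$required)
        if (!is.null(r$any_of))
            r$any_of$families <- unlist(r$any_of$families)
        r$forbidden <- as.character(unlist(r$forbidden))
        r$optional <- as.character(unlist(r$optional))
        r
    })
    rules <- rules[order(vapply(rules, `[[`, numeric(1), "priority"))]
    validateRules(rules)
    rules
}
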