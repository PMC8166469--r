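## Printed clinical composition of the cohorts the published 17-pair
## signature was built on: a TCGA colon-adenocarcinoma discovery cohort
## (n = 452) and a GEO microarray validation cohort (n = 585).

#' Published cohort composition counts
#'
#' Sex and tumour-stage counts, with cohort sizes and mean ages, for the
#' discovery (n = 452) and validation (n = 585) colon-cancer cohorts
#' underlying the published 17-pair signature. Useful for recomputing
#' composition percentages and for parameterising realistic simulations.
#'
#' @return data.frame with columns cohort ("discovery"/"validation"),
#'   variable ("sex"/"stage"), level, count and n (cohort size).
#' @examples
#' comp <- publishedCohortComposition()
#' cohortCompositionPercent(comp)
#' @export
publishedCohortComposition <- function() {
    data.frame(
        cohort = rep(c("discovery", "validation"), each = 7L),
        variable = rep(c("sex", "sex", "stage", "stage", "stage", "stage",
                         "stage"), 2L),
        level = rep(c("female", "male", "I", "II", "III", "IV", "unknown"),
                    2L),
        count = c(214L, 238L, 76L, 178L, 125L, 62L, 11L,
                  263L, 322L, 38L, 271L, 210L, 60L, 6L),
        n = rep(c(452L, 585L), each = 7L),
        stringsAsFactors = FALSE)
}

#' Cohort composition percentages
#'
#' Adds a \code{percent} column (100 x count / n) to a composition table.
#'
#' @param composition data.frame as from [publishedCohortComposition()].
#' @return the same data.frame with a percent column.
#' @export
cohortCompositionPercent <- function(composition) {
    stopifnot(all(c("count", "n") %in% colnames(composition)))
    composition$percent <- 100 * composition$count / composition$n
    composition
}

#' Published mean ages
#'
#' @return named numeric vector: mean age at diagnosis in the discovery
#'   and validation cohorts.
#' @export
publishedCohortAges <- function() {
    c(discovery = 67.09, validation = 66.95)
}
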