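# Bundled 59-codon RSCU reference profiles: published mean RSCU of the
# ORF1 gene sets of the two torque teno sus virus genera (TTSuV1 /
# Iotatorquevirus, TTSuV2 / Kappatorquevirus) and the codon usage of the
# two pig hosts, Sus scrofa and Sus scrofa domestica (as retrieved from
# the Kazusa Codon Usage Database).  Values are given to two decimals, so
# family sums hit the family size only to that precision.

#' Bundled RSCU reference profiles
#'
#' Returns the four bundled 59-codon RSCU profiles: `ttsuv1`, `ttsuv2`
#' (virus genus means over ORF1 gene sets), `sus_scrofa` and
#' `sus_scrofa_domestica` (host codon usage).  These back the worked
#' host-adaptation examples and the bundled host references of
#' [load_host_reference()].
#'
#' @return Named list of four `cub_rscu` profiles
#'   (`source = "external_table"`).
#' @export
#' @examples
#' p <- builtin_rscu_profiles()
#' coincidence_analysis(p$ttsuv1, p$sus_scrofa)
builtin_rscu_profiles <- function() {
  path <- system.file("extdata", "rscu_reference_profiles.tsv",
                      package = "cubkit", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- setdiff(names(tab), c("amino_acid", "codon"))
  stats::setNames(lapply(cols, function(cl)
    rscu_profile(stats::setNames(tab[[cl]], tab$codon))), cols)
}
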