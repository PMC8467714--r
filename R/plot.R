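#' Punnett-style plot of a two-locus incidence table
#'
#' Draws the nine genotype-cell incidences of a defect as bars with the
#' independent-loci expectation overlaid as open points; the gap between
#' bar and point is the higher-order interaction effect at that cell.
#'
#' @param table A [incidence_table()] with all nine cells populated.
#' @param main Plot title (defaults to defect and pair).
#' @return Invisibly, the decomposition used.
#' @export
plot_two_locus <- function(table, main = NULL) {
  stopifnot(inherits(table, "two_locus_table"))
  dec <- epistasis_decompose(table)
  obs <- as.vector(t(table$incidence))
  exp_ <- as.vector(t(dec$expected))
  labs <- as.vector(t(outer(0:2, 0:2, function(a, b) paste0(a, "/", b))))
  if (is.null(main)) {
    main <- paste0(table$defect, ": ", paste(table$pair, collapse = " x "))
  }
  bp <- graphics::barplot(obs, names.arg = labs, las = 2,
                          ylim = c(0, max(obs, exp_) * 1.2),
                          ylab = "incidence", main = main,
                          col = "grey80", border = NA)
  graphics::points(bp, exp_, pch = 1, cex = 1.3)
  graphics::abline(h = table$uwa, lty = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("observed", "expected", "UWA"),
                   pch = c(15, 1, NA), lty = c(NA, NA, 2),
                   col = c("grey80", "black", "black"))
  invisible(dec)
}

#' Bar chart of protective fractions by genotype class
#'
#' @param fractions Result of [protective_fractions()].
#' @return Invisibly, the per-class table plotted.
#' @export
plot_protective_fractions <- function(fractions) {
  bc <- fractions$by_class
  bp <- graphics::barplot(bc$fraction_protective,
                          names.arg = sub("_", "\n", bc$class),
                          ylim = c(0, 1), ylab = "fraction protective",
                          col = "grey70", border = NA)
  graphics::abline(h = 0.5, lty = 2)
  star <- !is.na(bc$p) & bc$p < 0.05
  if (any(star)) {
    graphics::text(bp[star], bc$fraction_protective[star] + 0.05, "*",
                   cex = 1.5)
  }
  invisible(bc)
}
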