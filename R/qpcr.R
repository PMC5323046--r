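#' Relative mRNA expression against a reference-gene geometric mean
#'
#' Classic efficiency-corrected relative quantification: per condition,
#' replicate Ct values are averaged on the Ct scale, expression is
#' `E^(-Ct)`, the target is normalized to the geometric mean of the
#' reference-gene expressions, and the result is the ratio of the
#' normalized expression in `condition` over `control`.
#'
#' Adding a constant to every Ct of a sample (global pipetting shift)
#' leaves the result unchanged, since the reference normalization cancels
#' it.
#'
#' @param ct `ct_table` data.frame (`sample`, `gene`, `replicate`, `ct`).
#' @param target Target gene.
#' @param condition,control Sample/condition labels.
#' @param reference_genes Reference gene set (default: the table's
#'   `reference_genes` attribute, else ACTB/HMBS/TBP).
#' @param efficiency Amplification factor per cycle in (1, 2] (default 2,
#'   perfect doubling). A named vector gives per-gene efficiencies.
#' @param average `"ct"` (default, mean Ct before transformation) or
#'   `"linear"` (mean of per-replicate linear quantities).
#' @return Fold-change of `condition` vs `control` (numeric).
#' @export
relative_expression <- function(ct, target, condition, control = "sicon",
                                reference_genes = NULL, efficiency = 2,
                                average = c("ct", "linear")) {
  average <- match.arg(average)
  need_cols(ct, c("sample", "gene", "ct"), "ct table")
  if (is.null(reference_genes)) {
    reference_genes <- attr(ct, "reference_genes") %||%
      c("ACTB", "HMBS", "TBP")
  }
  assert_that(all(ct$ct > 0), "relative_expression: Ct values must be > 0")
  eff_of <- function(g) {
    e <- if (!is.null(names(efficiency)) && g %in% names(efficiency)) {
      efficiency[[g]]
    } else {
      unname(efficiency[1])
    }
    assert_that(e > 1 && e <= 2,
                "relative_expression: efficiency must be in (1, 2]")
    e
  }
  expr_of <- function(gene, cond) {
    x <- ct$ct[ct$gene == gene & ct$sample == cond]
    if (!length(x)) {
      stop_named("relative_expression: gene %s not measured in sample %s",
                 gene, cond)
    }
    e <- eff_of(gene)
    if (average == "ct") e^(-mean(x)) else mean(e^(-x))
  }
  norm_of <- function(cond) {
    refs <- vapply(reference_genes, expr_of, numeric(1), cond = cond)
    expr_of(target, cond) / geomean(refs)
  }
  norm_of(condition) / norm_of(control)
}

#' Knockdown quality control against a residual-mRNA cutoff
#'
#' An siRNA passes when its relative mRNA level versus the non-targeting
#' control is strictly below the cutoff (default 0.65); levels at the
#' cutoff fail.
#'
#' @param levels Named numeric vector: siRNA -> relative mRNA level vs
#'   sicon.
#' @param cutoff Residual fraction boundary (default 0.65, strict).
#' @return List: `table` (data.frame `sirna`, `level`, `pass`),
#'   `pass_fraction`.
#' @export
#' @examples
#' knockdown_qc(c(a = 0.3, b = 0.65, c = 0.5, d = 0.9))$pass_fraction
knockdown_qc <- function(levels, cutoff = 0.65) {
  tab <- data.frame(sirna = names(levels) %||%
                      as.character(seq_along(levels)),
                    level = as.numeric(levels),
                    pass = as.numeric(levels) < cutoff,
                    stringsAsFactors = FALSE)
  list(table = tab, pass_fraction = mean(tab$pass))
}

#' ChIP-qPCR percent input with control normalization
#'
#' Computes `%input = 100 * 2^((Ct_input - log2(1 / input_fraction)) -
#' Ct_IP)`: the input Ct is first adjusted for the fraction of chromatin it
#' represents, then the IP signal is expressed relative to it. When a
#' matched control IP (`MOCK` for tagged-construct ChIP, `IgG` for
#' endogenous ChIP) is supplied, the percent input is divided by the
#' control's percent input at the same locus.
#'
#' @param ct_ip Ct of the specific IP.
#' @param ct_input Ct of the diluted input.
#' @param input_fraction Fraction of chromatin used as input, in (0, 1].
#' @param ct_control_ip,ct_control_input Optional Cts of the control IP and
#'   its input (input defaults to `ct_input`).
#' @return List: `percent_input`, `percent_input_control` (NA when no
#'   control), `normalized` (ratio vs control, or the raw percent input).
#' @export
#' @examples
#' chip_percent_input(25, 25, input_fraction = 1)$percent_input  # 100
chip_percent_input <- function(ct_ip, ct_input, input_fraction = 0.01,
                               ct_control_ip = NULL,
                               ct_control_input = NULL) {
  assert_that(input_fraction > 0 && input_fraction <= 1,
              "chip_percent_input: input_fraction must be in (0, 1]")
  pct <- function(ip, inp) {
    100 * 2^((inp - log2(1 / input_fraction)) - ip)
  }
  p <- pct(ct_ip, ct_input)
  if (is.null(ct_control_ip)) {
    return(list(percent_input = p, percent_input_control = NA_real_,
                normalized = p))
  }
  pc <- pct(ct_control_ip, ct_control_input %||% ct_input)
  list(percent_input = p, percent_input_control = pc, normalized = p / pc)
}
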