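#' Exosomal miRNA quantification and biomarker triage
#'
#' qPCR cycle-threshold (Ct) values are converted to relative expression by
#' the 2^-deltaCt method against the spiked-in cel-miR-39 reference, log
#' transformed, screened for differential expression between groups
#' (volcano-style fold-change/p thresholds on two contrasts), and validated
#' with covariate-adjusted ANCOVA plus post-hoc contrasts.
#'
#' @name mirna
NULL

#' 2^-deltaCt relative expression
#'
#' `deltaCt = ct - ct_ref`; expression `= 2^-deltaCt`. One extra cycle
#' relative to the reference halves the expression. Missing Ct values
#' propagate as `NA` with a warning rather than being dropped silently.
#'
#' @param ct cycle-threshold value(s) of the target miRNA.
#' @param ct_ref cycle-threshold of the spike-in reference (cel-miR-39).
#' @return relative expression, strictly positive where inputs are finite.
#' @export
delta_ct_expression <- function(ct, ct_ref) {
  out <- 2^(-(ct - ct_ref))
  if (anyNA(out)) warning("delta_ct_expression: ", sum(is.na(out)),
                          " missing Ct value(s) propagated as NA")
  out
}

#' Log-transform expression values
#'
#' @param expression positive expression values.
#' @param base logarithm base (natural log by default; `base = 2` recovers
#'   `-deltaCt` exactly from `delta_ct_expression()`).
#' @return log expression.
#' @export
log_expression <- function(expression, base = exp(1)) {
  if (any(expression <= 0, na.rm = TRUE))
    stop("log_expression: expression must be > 0")
  log(expression, base = base)
}

#' Build a miRNA panel from a Ct table
#'
#' @param ct_table data.frame with `subject_id`, optional `group`, one Ct
#'   column per miRNA, and the reference column.
#' @param ref_col name of the spike-in reference Ct column.
#' @param log_base base for `log_expression`.
#' @return object of class `mirna_panel`: `ct` (data.frame), `mirnas`
#'   (character), `expression` and `log_expression` (data.frames with
#'   subject_id/group carried through).
#' @export
mirna_panel <- function(ct_table, ref_col = "cel_mir_39", log_base = exp(1)) {
  if (!ref_col %in% names(ct_table))
    stop("mirna_panel: reference column '", ref_col, "' not found")
  meta <- intersect(c("subject_id", "group"), names(ct_table))
  mirnas <- setdiff(names(ct_table), c(meta, ref_col))
  if (!length(mirnas)) stop("mirna_panel: no miRNA Ct columns")
  expr <- ct_table[meta]
  lexpr <- ct_table[meta]
  for (m in mirnas) {
    e <- delta_ct_expression(ct_table[[m]], ct_table[[ref_col]])
    expr[[m]] <- e
    lexpr[[m]] <- log_expression(e, base = log_base)
  }
  structure(list(ct = ct_table, ref_col = ref_col, mirnas = mirnas,
                 expression = expr, log_expression = lexpr,
                 log_base = log_base),
            class = "mirna_panel")
}

.welch_t_p <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  stats::t.test(a, b)$p.value
}

#' Screen for differentially expressed miRNAs
#'
#' For each miRNA and contrast, computes the log2 fold change of group
#' means (on the linear expression scale) and a Welch t-test p-value on
#' log2-transformed values. Candidates must pass *both* contrasts with
#' `|log2FC| > lfc_threshold` (strict) and `p < p_threshold`, with a
#' consistent direction.
#'
#' @param expr data.frame or matrix of positive expression values (or
#'   normalized counts), subjects in rows, miRNAs in columns.
#' @param groups group label per subject.
#' @param contrasts list of 2-vectors `c(test_group, reference_group)`;
#'   default: HT-CI vs control and HT-CI vs HT-NC.
#' @param lfc_threshold,p_threshold candidate thresholds (defaults 1.0,
#'   0.05).
#' @param p_adjust optional multiplicity adjustment applied per contrast
#'   (`"none"` default; `"BH"` available).
#' @return object of class `screen_result`: `table` (tidy per
#'   miRNA x contrast), `candidates` (data.frame miRNA + direction),
#'   thresholds.
#' @export
screen_differential <- function(expr, groups,
                                contrasts = list(c("HT-CI", "control"),
                                                 c("HT-CI", "HT-NC")),
                                lfc_threshold = 1, p_threshold = 0.05,
                                p_adjust = "none") {
  expr <- as.data.frame(expr)
  groups <- as.character(groups)
  rows <- list()
  for (ct in contrasts) {
    if (!all(ct %in% groups))
      stop("screen_differential: group(s) absent: ",
           paste(setdiff(ct, groups), collapse = ", "))
    ia <- groups == ct[1]; ib <- groups == ct[2]
    if (sum(ia) < 2L || sum(ib) < 2L)
      stop("screen_differential: need >= 2 subjects per group")
    for (m in names(expr)) {
      a <- expr[[m]][ia]; b <- expr[[m]][ib]
      keep_a <- !is.na(a); keep_b <- !is.na(b)
      l2fc <- log2(mean(a[keep_a]) / mean(b[keep_b]))
      p <- .welch_t_p(log2(a[keep_a]), log2(b[keep_b]))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = m, contrast = paste(ct, collapse = "_vs_"),
        log2fc = l2fc, p = p, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::ave(tab$p, tab$contrast,
                          FUN = function(p) stats::p.adjust(p, p_adjust))
  p_used <- if (p_adjust == "none") tab$p else tab$p_adj
  tab$pass <- abs(tab$log2fc) > lfc_threshold & p_used < p_threshold
  cand <- lapply(split(tab, tab$mirna), function(d) {
    if (all(d$pass) && length(unique(sign(d$log2fc))) == 1L)
      data.frame(mirna = d$mirna[1],
                 direction = if (d$log2fc[1] > 0) "up" else "down",
                 stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
  if (is.null(cand))
    cand <- data.frame(mirna = character(0), direction = character(0))
  rownames(cand) <- NULL
  structure(list(table = tab, candidates = cand,
                 lfc_threshold = lfc_threshold, p_threshold = p_threshold,
                 p_adjust = p_adjust),
            class = "screen_result")
}

#' Validate candidate miRNAs with covariate-adjusted ANCOVA
#'
#' Per candidate miRNA, fits log expression ~ group + covariates and
#' reports the adjusted group F/p plus pairwise adjusted contrasts
#' (delegating to [ancova()]).
#'
#' @param panel a [mirna_panel()].
#' @param cohort data.frame with `subject_id`, `group`, and the covariate
#'   columns.
#' @param candidates miRNA names to validate (default: all in the panel).
#' @param covariates covariate column names in `cohort`.
#' @param p_adjust post-hoc adjustment passed to [ancova()].
#' @return list of class `validation_result`: `anova` (data.frame per
#'   miRNA: F, p, df), `contrasts` (tidy data.frame), `covariates`.
#' @export
validate_candidates <- function(panel, cohort, candidates = NULL,
                                covariates = c("age", "education_years",
                                               "lacunar_stroke"),
                                p_adjust = "none") {
  stopifnot(inherits(panel, "mirna_panel"))
  if (is.null(candidates)) candidates <- panel$mirnas
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov))
    stop("validate_candidates: covariate columns missing: ",
         paste(missing_cov, collapse = ", "))
  le <- panel$log_expression
  idx <- match(le$subject_id, cohort$subject_id)
  if (anyNA(idx)) stop("validate_candidates: subjects not in cohort table")
  grp <- cohort$group[idx]
  covs <- if (length(covariates)) cohort[idx, covariates, drop = FALSE] else NULL
  an_rows <- list(); ct_rows <- list()
  for (m in candidates) {
    res <- ancova(le[[m]], grp, covs, p_adjust = p_adjust)
    an_rows[[m]] <- data.frame(mirna = m, F = res$F, p = res$p,
                               df1 = res$df[1], df2 = res$df[2],
                               stringsAsFactors = FALSE)
    cc <- res$contrasts; cc$mirna <- m
    ct_rows[[m]] <- cc
  }
  structure(list(anova = do.call(rbind, c(an_rows, make.row.names = FALSE)),
                 contrasts = do.call(rbind, c(ct_rows, make.row.names = FALSE)),
                 covariates = covariates),
            class = "validation_result")
}
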