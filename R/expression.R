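# Housekeeping-normalized qPCR relative expression and protease ratio.

#' Relative expression by housekeeping normalization
#'
#' \eqn{rel = E^{-\Delta Ct}} with \eqn{\Delta Ct = Ct_{gene} -
#' Ct_{housekeeping}} per animal per gene; the default efficiency `E = 2`
#' is the usual 100%-efficiency assumption. The housekeeping gene
#' normalizes to itself, so `rel` is exactly 1 for it. Animals missing a
#' housekeeping Ct are excluded with a warning.
#'
#' @param ct_table data.frame with columns `animal_id`, `group`, `gene`,
#'   `ct` (one finite Ct per animal x gene).
#' @param housekeeping housekeeping gene name (default `"RPL13a"`).
#' @param efficiency amplification efficiency base; scalar or named
#'   per-gene vector (default 2).
#' @return data.frame with columns `animal_id`, `group`, `gene`, `rel`.
#' @export
relative_expression <- function(ct_table, housekeeping = "RPL13a",
                                efficiency = 2) {
  need <- c("animal_id", "group", "gene", "ct")
  stopifnot(all(need %in% names(ct_table)))
  if (!housekeeping %in% ct_table$gene)
    stop(sprintf("housekeeping gene '%s' absent from table", housekeeping))
  if (anyNA(ct_table$ct) || any(!is.finite(ct_table$ct)) ||
      any(ct_table$ct <= 0))
    stop("all Ct values must be finite and > 0")
  if (anyDuplicated(ct_table[, c("animal_id", "gene")]))
    stop("more than one Ct per animal x gene")
  hk <- ct_table[ct_table$gene == housekeeping, c("animal_id", "ct")]
  names(hk)[2L] <- "ct_hk"
  missing_hk <- setdiff(unique(ct_table$animal_id), hk$animal_id)
  if (length(missing_hk)) {
    warning(sprintf("excluding %d animal(s) without a %s Ct: %s",
                    length(missing_hk), housekeeping,
                    paste(missing_hk, collapse = ", ")))
    ct_table <- ct_table[!ct_table$animal_id %in% missing_hk, , drop = FALSE]
  }
  m <- merge(ct_table, hk, by = "animal_id", sort = FALSE)
  eff <- if (length(efficiency) == 1L && is.null(names(efficiency)))
    rep_len(efficiency, nrow(m))
  else {
    e <- unname(efficiency[m$gene])
    if (anyNA(e)) stop("per-gene `efficiency` must name every gene")
    e
  }
  out <- data.frame(animal_id = m$animal_id, group = m$group, gene = m$gene,
                    rel = eff^(-(m$ct - m$ct_hk)),
                    stringsAsFactors = FALSE)
  out[order(out$animal_id, out$gene), , drop = FALSE]
}

#' Per-animal MMP-9 : TIMP-1 expression ratio
#'
#' The protease/antiprotease balance readout: for each animal, relative
#' MMP-9 expression divided by relative TIMP-1 expression (the
#' housekeeping Ct cancels algebraically, so the ratio equals
#' \eqn{2^{-(Ct_{MMP9} - Ct_{TIMP1})}} under the default efficiency).
#' Group summaries are reported as the arithmetic mean +/- SEM over
#' animals, mirroring the usual ratio +/- SEM display, together with a
#' log2-scale summary since ratios are log-normal.
#'
#' @param rel a [relative_expression()] result.
#' @param numerator,denominator gene names (defaults `"MMP9"`, `"TIMP1"`).
#' @return list with `per_animal` (animal_id, group, ratio) and
#'   `per_group` / `per_group_log2` summaries.
#' @export
mmp9_timp1_ratio <- function(rel, numerator = "MMP9", denominator = "TIMP1") {
  stopifnot(all(c("animal_id", "group", "gene", "rel") %in% names(rel)))
  num <- rel[rel$gene == numerator, c("animal_id", "group", "rel")]
  den <- rel[rel$gene == denominator, c("animal_id", "rel")]
  names(num)[3L] <- "rel_num"; names(den)[2L] <- "rel_den"
  no_den <- setdiff(num$animal_id, den$animal_id)
  m <- merge(num, den, by = "animal_id", sort = FALSE)
  bad <- is.na(m$rel_den) | m$rel_den <= 0 | is.na(m$rel_num)
  excl <- c(no_den, m$animal_id[bad])
  if (length(excl))
    warning(sprintf("excluding %d animal(s) with missing/zero %s expression: %s",
                    length(excl), denominator, paste(excl, collapse = ", ")))
  m <- m[!bad, , drop = FALSE]
  per_animal <- data.frame(animal_id = m$animal_id, group = m$group,
                           ratio = m$rel_num / m$rel_den,
                           stringsAsFactors = FALSE)
  list(per_animal = per_animal,
       per_group = group_summary(per_animal$ratio, per_animal$group),
       per_group_log2 = group_summary(log2(per_animal$ratio),
                                      per_animal$group))
}
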