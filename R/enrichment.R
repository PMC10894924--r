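#' Over-representation of module genes in gene-set collections
#'
#' Splits the module's genes by the sign of their mean log2FC into up- and
#' downregulated queries and tests each against every gene set with the
#' one-sided hypergeometric (Fisher) upper tail
#' `P(X >= overlap)`, using the supplied background as the universe.
#' Sets are intersected with the background first; by default sets smaller
#' than `min_set` or larger than half the background are skipped. BH
#' adjustment across sets per (module, direction).
#'
#' @param module_genes Character vector of module gene ids (subset of
#'   `background`).
#' @param de A [moderated_de()] result supplying per-gene mean log2FC.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Character vector: the gene universe (e.g. all genes that
#'   survived filtering).
#' @param min_set,max_set_fraction Set-size hygiene bounds (defaults 5 and
#'   0.5).
#' @return Data frame with columns `direction`, `set`, `overlap`, `set_size`,
#'   `query_size`, `background_size`, `odds_ratio`, `p`, `padj`.
#' @export
overrepresentation <- function(module_genes, de, collection, background,
                               min_set = 5, max_set_fraction = 0.5) {
  if (length(background) == 0) stop("background is empty", call. = FALSE)
  bad <- setdiff(module_genes, background)
  if (length(bad))
    stop("module gene(s) missing from background: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  lfc <- stats::setNames(de$log2fc, de$gene)[module_genes]
  queries <- list(up = module_genes[!is.na(lfc) & lfc > 0],
                  down = module_genes[!is.na(lfc) & lfc < 0])
  N <- length(background)
  rows <- list()
  for (dir in names(queries)) {
    q <- queries[[dir]]
    if (length(q) == 0) next
    for (nm in names(collection)) {
      s <- intersect(collection[[nm]], background)
      if (length(s) < min_set || length(s) > max_set_fraction * N) next
      k <- length(intersect(q, s))
      p <- stats::phyper(k - 1, length(s), N - length(s), length(q),
                         lower.tail = FALSE)
      or <- (k * (N - length(s) - length(q) + k)) /
        max((length(s) - k) * (length(q) - k), .Machine$double.eps)
      rows[[length(rows) + 1L]] <- data.frame(
        direction = dir, set = nm, overlap = k, set_size = length(s),
        query_size = length(q), background_size = N, odds_ratio = or,
        p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(direction = character(0), set = character(0),
                      overlap = integer(0), set_size = integer(0),
                      query_size = integer(0), background_size = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      padj = numeric(0)))
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  for (dir in unique(out$direction)) {
    sel <- out$direction == dir
    out$padj[sel] <- adjust_fdr(out$p[sel])
  }
  out
}

#' Cross-module regulation enrichment
#'
#' Asks whether the targets of one module's transcription factors are
#' over-represented inside another module: the query is the union of all
#' targets of TFs assigned to `source_module`, tested against the genes of
#' `target_module` with a one-sided hypergeometric tail over the background.
#'
#' @param regulons A regulon set (named list of data frames with a `target`
#'   column, as produced by [aracne_network()]).
#' @param labels Named gene -> module labels.
#' @param source_module,target_module Module ids.
#' @param background Gene universe.
#' @return One-row data frame: `n_tfs`, `overlap`, `query_size`,
#'   `target_module_size`, `background_size`, `p`.
#' @export
cross_module_regulation_test <- function(regulons, labels, source_module,
                                         target_module, background) {
  tfs <- intersect(names(regulons),
                   names(labels)[labels == source_module])
  if (length(tfs) == 0)
    stop(sprintf("no TFs of module %s present in the regulon set",
                 source_module), call. = FALSE)
  query <- intersect(unique(unlist(lapply(regulons[tfs],
                                          function(r) r$target))), background)
  tmod <- intersect(names(labels)[labels == target_module], background)
  if (length(tmod) == 0) stop("target module is empty", call. = FALSE)
  k <- length(intersect(query, tmod))
  N <- length(background)
  p <- stats::phyper(k - 1, length(tmod), N - length(tmod), length(query),
                     lower.tail = FALSE)
  data.frame(source_module = source_module, target_module = target_module,
             n_tfs = length(tfs), overlap = k, query_size = length(query),
             target_module_size = length(tmod), background_size = N, p = p,
             stringsAsFactors = FALSE)
}
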