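#' Classify per-gene screen hits as enriched, depleted, or neutral
#'
#' A knockout whose sgRNAs become enriched under immune pressure marks a
#' sensitizer candidate (its normal function promotes immune killing), a
#' depleted knockout marks a resistor candidate. Thresholds are strict:
#' enriched iff `adj_p_pos < alpha` and `lfc > 0`; depleted iff
#' `adj_p_neg < alpha` and `lfc < 0`.
#'
#' @param hits data.frame from [read_screen_hits()].
#' @param alpha Significance level for the adjusted p-values (default 0.05).
#' @return The input with an added factor column `call` in
#'   \{enriched, depleted, neutral\}.
#' @export
classify_hits <- function(hits, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  lfc <- hits$lfc
  n_missing <- sum(is.na(lfc))
  if (n_missing > 0) {
    warning(sprintf("%d record(s) with missing lfc set to neutral", n_missing))
  }
  enriched <- !is.na(lfc) & !is.na(hits$adj_p_pos) &
    hits$adj_p_pos < alpha & lfc > 0
  depleted <- !is.na(lfc) & !is.na(hits$adj_p_neg) &
    hits$adj_p_neg < alpha & lfc < 0
  call <- rep("neutral", nrow(hits))
  call[enriched] <- "enriched"
  call[depleted] <- "depleted"
  hits$call <- factor(call, levels = c("enriched", "depleted", "neutral"))
  hits
}

#' Map gene symbols through an ortholog table
#'
#' Mouse screen hits are lifted to human symbols with a user-supplied
#' two-column table. Genes without a mapping are dropped (and counted);
#' a source gene with several human orthologs expands to all of them.
#'
#' @param genes Character vector of source symbols.
#' @param ortholog_table data.frame with columns `source` and `human`.
#' @return Character vector of human symbols, input order preserved, with
#'   attributes `n_dropped` and `n_expanded`.
#' @export
map_orthologs <- function(genes, ortholog_table) {
  stopifnot(all(c("source", "human") %in% names(ortholog_table)))
  if (length(genes) == 0) {
    return(structure(character(), n_dropped = 0L, n_expanded = 0L))
  }
  idx <- split(seq_len(nrow(ortholog_table)), ortholog_table$source)
  out <- vector("list", length(genes))
  n_dropped <- 0L
  n_expanded <- 0L
  for (i in seq_along(genes)) {
    rows <- idx[[genes[i]]]
    if (is.null(rows)) {
      n_dropped <- n_dropped + 1L
      out[[i]] <- character()
    } else {
      targets <- unique(ortholog_table$human[rows])
      if (length(targets) > 1) n_expanded <- n_expanded + 1L
      out[[i]] <- targets
    }
  }
  res <- unlist(out, use.names = FALSE)
  if (n_dropped > 0) {
    iscreen_log("map_orthologs: dropped %d gene(s) without a human ortholog",
                n_dropped)
  }
  if (n_expanded > 0) {
    iscreen_log("map_orthologs: %d gene(s) expanded one-to-many", n_expanded)
  }
  structure(res, n_dropped = n_dropped, n_expanded = n_expanded)
}

#' Build a recurrent sensitizer/resistor catalog from classified screens
#'
#' A gene enters the catalog as a sensitizer when it is enriched in at
#' least `min_screens` screens, as a resistor when depleted in at least
#' `min_screens`. A gene qualifying for both roles keeps the role with
#' more supporting screens; ties are excluded and logged.
#'
#' @param classified Named list of data.frames from [classify_hits()]; names
#'   (or `screen_id` attributes) identify the screens.
#' @param min_screens Recurrence threshold (default 2).
#' @return data.frame with columns `gene`, `role`, `support`
#'   (comma-separated screen ids), `n_screens`.
#' @export
build_catalog <- function(classified, min_screens = 2) {
  stopifnot(min_screens >= 1)
  if (length(classified) < min_screens) {
    stop(sprintf("need at least %d screens, got %d",
                 min_screens, length(classified)), call. = FALSE)
  }
  ids <- names(classified)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- vapply(seq_along(classified), function(i) {
      attr(classified[[i]], "screen_id") %||% paste0("screen", i)
    }, character(1))
  }
  support <- list(sensitizer = list(), resistor = list())
  for (i in seq_along(classified)) {
    tab <- classified[[i]]
    enr <- unique(tab$gene[tab$call == "enriched"])
    dep <- unique(tab$gene[tab$call == "depleted"])
    for (g in enr) support$sensitizer[[g]] <- c(support$sensitizer[[g]], ids[i])
    for (g in dep) support$resistor[[g]] <- c(support$resistor[[g]], ids[i])
  }
  all_genes <- union(names(support$sensitizer), names(support$resistor))
  rows <- lapply(all_genes, function(g) {
    ns <- length(support$sensitizer[[g]] %||% character())
    nr <- length(support$resistor[[g]] %||% character())
    if (ns >= min_screens && nr >= min_screens) {
      if (ns == nr) {
        iscreen_log("build_catalog: %s tied between roles (%d vs %d), excluded",
                    g, ns, nr)
        return(NULL)
      }
      role <- if (ns > nr) "sensitizer" else "resistor"
    } else if (ns >= min_screens) {
      role <- "sensitizer"
    } else if (nr >= min_screens) {
      role <- "resistor"
    } else {
      return(NULL)
    }
    sup <- sort(support[[role]][[g]])
    data.frame(gene = g, role = role,
               support = paste(sup, collapse = ","),
               n_screens = length(sup), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(gene = character(), role = character(),
                      support = character(), n_screens = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
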