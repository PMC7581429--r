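#' Genes concordantly differentially expressed versus both parents
#'
#' A gene is concordant at a timepoint when it is significant
#' (adjusted p below `max_adjusted_p`, |log2 fold change| at or above
#' `min_abs_log2fc`) versus *both* parents with the *same* fold-change sign.
#' Genes with only one parental comparison are excluded (and reported via
#' the `dropped_single_comparison` attribute).
#'
#' @param det_tbl DET tibble from [read_det_table()].
#' @param timepoint `"d0"` or `"d25"`.
#' @param config A [concordance_config()].
#' @return Character vector of concordant gene symbols.
#' @export
concordant_dets <- function(det_tbl, timepoint = c("d0", "d25"),
                            config = concordance_config()) {
  timepoint <- match.arg(timepoint)
  tp <- det_tbl[det_tbl$timepoint == timepoint, ]
  wide <- tp |>
    dplyr::select("gene", "comparison", "log2fc", "adjusted_p") |>
    tidyr::pivot_wider(names_from = "comparison",
                       values_from = c("log2fc", "adjusted_p"))
  for (col in c("log2fc_proband_vs_mother", "log2fc_proband_vs_father",
                "adjusted_p_proband_vs_mother", "adjusted_p_proband_vs_father")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  single <- wide$gene[is.na(wide$log2fc_proband_vs_mother) |
                        is.na(wide$log2fc_proband_vs_father)]
  ok <- !wide$gene %in% single &
    wide$adjusted_p_proband_vs_mother < config$max_adjusted_p &
    wide$adjusted_p_proband_vs_father < config$max_adjusted_p &
    abs(wide$log2fc_proband_vs_mother) >= config$min_abs_log2fc &
    abs(wide$log2fc_proband_vs_father) >= config$min_abs_log2fc &
    sign(wide$log2fc_proband_vs_mother) == sign(wide$log2fc_proband_vs_father)
  res <- sort(wide$gene[ok])
  attr(res, "dropped_single_comparison") <- single
  res
}

#' Concordance configuration
#'
#' @param max_adjusted_p FDR-adjusted p-value cutoff (strictly below).
#' @param min_abs_log2fc Minimum absolute log2 fold change (inclusive);
#'   default 1 (two-fold), configurable because the magnitude cutoff of the
#'   original expression pipeline is not recoverable.
#' @param require_timepoints Timepoints a final candidate must be concordant
#'   at.
#' @return A list of class `concordance_config`.
#' @export
concordance_config <- function(max_adjusted_p = 0.05, min_abs_log2fc = 1,
                               require_timepoints = c("d0", "d25")) {
  stopifnot(max_adjusted_p > 0, max_adjusted_p < 1, min_abs_log2fc >= 0)
  structure(list(max_adjusted_p = max_adjusted_p,
                 min_abs_log2fc = min_abs_log2fc,
                 require_timepoints = require_timepoints),
            class = "concordance_config")
}

#' Intersect inheritance calls with differential-expression evidence
#'
#' Final candidates are genes carrying an inheritance call AND concordantly
#' differentially expressed at both timepoints. Never introduces genes
#' beyond the call set.
#'
#' @param calls Inheritance-call tibble (`calls` element of a
#'   `cascade_result`).
#' @param det_d0,det_d25 Concordant gene sets from [concordant_dets()].
#' @return The call rows of the final candidate genes.
#' @export
intersect_candidates <- function(calls, det_d0, det_d25) {
  calls[calls$gene %in% det_d0 & calls$gene %in% det_d25, ]
}

#' First-neighbor interaction subnetwork around seed genes
#'
#' Induced subgraph on the seeds plus every gene directly interacting with a
#' seed. Self-loops are dropped and duplicate edges collapsed with the union
#' of their interaction types. Seeds absent from the edge list are retained
#' as isolated nodes with a warning.
#'
#' @param seed_genes Character vector of seed gene symbols.
#' @param edges Tibble with columns `gene_a`, `gene_b` and optionally
#'   `type`.
#' @return List with `nodes` (tibble `node`, `is_seed`, `degree`) and
#'   `edges` (tibble `gene_a`, `gene_b`, `type`).
#' @export
first_neighbor_network <- function(seed_genes, edges) {
  if (!"type" %in% names(edges)) edges$type <- "interaction"
  edges <- edges[edges$gene_a != edges$gene_b, ]  # self-loops out
  # undirected duplicate collapse with type union
  edges <- edges |>
    dplyr::mutate(.lo = pmin(.data$gene_a, .data$gene_b),
                  .hi = pmax(.data$gene_a, .data$gene_b)) |>
    dplyr::group_by(.data$.lo, .data$.hi) |>
    dplyr::summarise(type = paste(sort(unique(.data$type)), collapse = ";"),
                     .groups = "drop") |>
    dplyr::rename(gene_a = ".lo", gene_b = ".hi")
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  present <- intersect(seed_genes, igraph::V(g)$name)
  missing <- setdiff(seed_genes, present)
  if (length(missing) > 0) {
    warning("Seed gene(s) absent from the edge list kept as isolated nodes: ",
            paste(missing, collapse = ", "))
  }
  nbrs <- if (length(present) > 0) {
    unique(unlist(lapply(igraph::ego(g, order = 1, nodes = present),
                         function(v) v$name)))
  } else character(0)
  nodes <- sort(unique(c(seed_genes, nbrs)))
  sub_edges <- edges[edges$gene_a %in% nodes & edges$gene_b %in% nodes, ]
  # keep only edges touching a seed or between neighbors both tied to seeds;
  # the induced subgraph on seeds + first neighbors keeps all edges among them
  deg <- table(c(sub_edges$gene_a, sub_edges$gene_b))
  list(
    nodes = tibble::tibble(node = nodes,
                           is_seed = nodes %in% seed_genes,
                           degree = as.integer(ifelse(nodes %in% names(deg),
                                                      deg[nodes], 0L))),
    edges = sub_edges
  )
}
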