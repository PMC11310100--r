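#' Reference module gene-count table
#'
#' The reported gene-module size table for the three spatial scales at
#' which the co-expression decomposition was run on the Allen-atlas
#' expression matrix (5093 retained genes), bundled as plain TSV. Each
#' scale lists its module sizes (including the unassigned "gray" module)
#' and an `All` row with the reported total; the per-module counts at
#' every scale sum to that same total, a bookkeeping identity used in the
#' package's consistency checks.
#'
#' @return data.frame with columns `scale, module, n_genes`.
#' @export
referenceModuleCounts <- function() {
  read.delim(system.file("extdata", "module_gene_counts.tsv",
                         package = "rehomics"))
}
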