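# Re-exported generics so downstream code can use the standard accessors
# on SplicingExperiment objects without attaching the Bioconductor stack.

#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData

#' @importFrom SummarizedExperiment rowData
#' @export
SummarizedExperiment::rowData

#' @importFrom SummarizedExperiment assay
#' @export
SummarizedExperiment::assay

#' @importFrom S4Vectors metadata
#' @export
S4Vectors::metadata
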