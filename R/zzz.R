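#' @import data.table
#' @importFrom stats setNames
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", "cell_id", "subgroup", "donor", "region", "cell_type",
  "disease", "sex", "age", "value", "chrom", "window_start", "sample",
  "n", "i", "j"))
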