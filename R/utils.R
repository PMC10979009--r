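#' @importFrom rlang .data %||%
#' @importFrom dplyr n
NULL

utils::globalVariables(c("fold_increase", "s_um"))
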