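#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort .data :=
NULL

# Error taxonomy: every condition the package raises carries a stable `code`
# and a condition class "msamap_<lowercase code>" so callers (and the CLI)
# can dispatch without string-matching messages.
msamap_abort <- function(code, message, ...) {
  abort(
    message,
    class = c(paste0("msamap_", tolower(code)), "msamap_error"),
    code = code,
    ...
  )
}

# exit-code classes used by the CLI: 2 usage, 3 validation, 4 data/config
.validation_codes <- c(
  "PARSE_ERROR", "TOO_MANY_RANGES", "RANGE_TOO_LONG",
  "ENDPOINTS_OUT_OF_ORDER", "UNKNOWN_RESIDUE", "NO_DATA"
)
.data_codes <- c(
  "FORMAT_ERROR", "DUPLICATE_ID", "DUPLICATE_RESIDUE_KEY", "EMPTY_INPUT",
  "INVALID_ALIGNMENT", "LOOKUP_NOT_FOUND", "LOOKUP_MISMATCH",
  "CONFIG_ERROR", "UNKNOWN_STRUCTURE", "AMBIGUOUS_ALIGNMENT"
)
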