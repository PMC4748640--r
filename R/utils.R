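`%||%` <- function(a, b) if (is.null(a)) b else a

## split a gapped row into single characters once; used in several hot paths
.chars <- function(row) strsplit(row, "", fixed = TRUE)[[1L]]

## 1-based residue position -> 1-based alignment column, per row
## row_chars: character vector of one gapped row
.residue_columns <- function(row_chars) which(row_chars != "-")

.stop_config <- function(...) {
  stop(structure(class = c("famHotspot_config_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

.stop_data <- function(...) {
  stop(structure(class = c("famHotspot_data_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}
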