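# Classed error conditions used across the package. Every maskqc error
# inherits from "maskqc_error" so callers can catch the family at once.

maskqc_error <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "maskqc_error"), call = call))
}

empty_mask_error <- function(msg = "mask has no foreground voxels") {
  maskqc_error("empty_mask_error", msg)
}

config_error <- function(msg) {
  maskqc_error("config_error", msg)
}

insufficient_data_error <- function(msg) {
  maskqc_error("insufficient_data_error", msg)
}

degenerate_clustering_error <- function(msg) {
  maskqc_error("degenerate_clustering_error", msg)
}

grid_mismatch_error <- function(msg) {
  maskqc_error("grid_mismatch_error", msg)
}
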