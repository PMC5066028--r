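#' Montage configuration
#'
#' A montage declares the ordered channel list, which channels form
#' left/right symmetric pairs, which sit on the midline, and optional named
#' subsets (e.g. `motor_cortex`). All spatial bookkeeping downstream
#' (hemisphere-lateralized synthesis, channel selection, asymmetry pairs)
#' goes through a montage rather than through positional assumptions.
#'
#' @param channel_names ordered channel identifiers (10-10 names).
#' @param left_right_pairs list of `c(left, right)` character pairs.
#' @param midline channels assigned to neither hemisphere.
#' @param subsets named list of character vectors, each a channel subset.
#' @return an object of class `montage_config`.
#' @export
montage_config <- function(channel_names, left_right_pairs, midline = character(),
                           subsets = list()) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stop_config("duplicate channel names in montage")
  paired <- unlist(left_right_pairs)
  missing <- setdiff(c(paired, midline, unlist(subsets)), channel_names)
  if (length(missing))
    stop_config("montage refers to unknown channels: %s",
                paste(missing, collapse = ", "))
  if (anyDuplicated(paired))
    stop_config("a channel may belong to at most one symmetric pair")
  structure(list(channel_names = channel_names,
                 left_right_pairs = lapply(left_right_pairs, as.character),
                 midline = as.character(midline),
                 subsets = subsets),
            class = "montage_config")
}

#' Default 14-channel montage
#'
#' A whole-scalp 14-channel layout built from the five symmetric
#' sensorimotor pairs FC5-FC6, FC1-FC2, C3-C4, CP5-CP6, P1-P2 plus four
#' midline channels (Fz, Cz, Pz, Oz). Note the four non-pair channels are a
#' reconstruction chosen to cover frontal, central, parietal and occipital
#' regions; override via [montage_config()] when a recording's montage is
#' known exactly.
#'
#' @return a `montage_config`.
#' @export
default_montage <- function() {
  pairs <- list(c("FC5", "FC6"), c("FC1", "FC2"), c("C3", "C4"),
                c("CP5", "CP6"), c("P1", "P2"))
  montage_config(
    channel_names = c("FC5", "FC1", "FC2", "FC6", "C3", "C4",
                      "CP5", "CP6", "P1", "P2", "Fz", "Cz", "Pz", "Oz"),
    left_right_pairs = pairs,
    midline = c("Fz", "Cz", "Pz", "Oz"),
    subsets = list(motor_cortex = c("FC5", "FC1", "FC2", "FC6",
                                    "C3", "C4", "CP5", "CP6"))
  )
}

# hemisphere membership: +1 left, -1 right, 0 midline/unpaired
montage_hemisphere <- function(montage) {
  h <- setNames(rep(0, length(montage$channel_names)), montage$channel_names)
  for (p in montage$left_right_pairs) {
    h[p[1L]] <- 1
    h[p[2L]] <- -1
  }
  h
}

#' @export
print.montage_config <- function(x, ...) {
  cat("Montage:", length(x$channel_names), "channels\n")
  cat("  pairs:", paste(vapply(x$left_right_pairs, paste, "", collapse = "-"),
                        collapse = ", "), "\n")
  cat("  midline:", paste(x$midline, collapse = ", "), "\n")
  if (length(x$subsets))
    cat("  subsets:", paste(names(x$subsets), collapse = ", "), "\n")
  invisible(x)
}
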