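#' Build the block/epoch sampling grid
#'
#' Scoring happens on 25 s epochs cut from 115 s blocks of artifact-free N2
#' sleep: each block yields 5 epochs at offsets 0, 22.5, 45, 67.5 and 90 s, so
#' consecutive epochs overlap by 2.5 s and the five epochs exactly tile the
#' block (25 + 4 x 22.5 = 115 s).
#'
#' @param block_starts Numeric vector of block start times in seconds from
#'   recording start. Blocks are `block_length_s` long and must not overlap.
#' @param fs Sampling rate of the processed signal, default 100 Hz.
#' @param block_length_s Block length in seconds, default 115.
#' @param epoch_length_s Epoch length in seconds, default 25.
#' @param epoch_stride_s Offset between consecutive epoch starts, default 22.5
#'   (2.5 s overlap).
#' @return An `epoch_grid`: a tibble with one row per epoch and columns
#'   `epoch_id` ("b<i>e<j>", 0-based), `block`, `epoch`, `start_s`, `end_s`,
#'   carrying `fs` and the block geometry as attributes.
#' @examples
#' g <- build_epoch_grid(0)
#' g$start_s # 0 22.5 45 67.5 90
#' @export
build_epoch_grid <- function(block_starts, fs = 100, block_length_s = 115,
                             epoch_length_s = 25, epoch_stride_s = 22.5) {
  block_starts <- as.numeric(block_starts)
  if (length(block_starts) == 0) {
    g <- tibble::tibble(
      epoch_id = character(), block = integer(), epoch = integer(),
      start_s = numeric(), end_s = numeric()
    )
    return(new_epoch_grid(g, fs, block_length_s, epoch_length_s, epoch_stride_s))
  }
  ord <- order(block_starts)
  bs <- block_starts[ord]
  if (any(diff(bs) < block_length_s - 1e-9)) {
    i <- which(diff(bs) < block_length_s - 1e-9)[1]
    stop(sprintf(
      "blocks starting at %g s and %g s overlap (blocks are %g s long).",
      bs[i], bs[i + 1], block_length_s
    ), call. = FALSE)
  }
  n_ep <- floor((block_length_s - epoch_length_s) / epoch_stride_s + 1e-9) + 1
  g <- tidyr::expand_grid(
    block = seq_along(bs) - 1L,
    epoch = seq_len(n_ep) - 1L
  ) |>
    dplyr::mutate(
      epoch_id = sprintf("b%de%d", .data$block, .data$epoch),
      start_s = bs[.data$block + 1L] + .data$epoch * epoch_stride_s,
      end_s = .data$start_s + epoch_length_s
    ) |>
    dplyr::select("epoch_id", "block", "epoch", "start_s", "end_s")
  new_epoch_grid(g, fs, block_length_s, epoch_length_s, epoch_stride_s)
}

new_epoch_grid <- function(g, fs, block_length_s, epoch_length_s, epoch_stride_s) {
  structure(
    g,
    fs = fs,
    block_length_s = block_length_s,
    epoch_length_s = epoch_length_s,
    epoch_stride_s = epoch_stride_s,
    class = c("epoch_grid", class(tibble::tibble()))
  )
}

#' Total scored time covered by a grid
#'
#' @param grid An [build_epoch_grid()] result.
#' @return Unique scored signal time in seconds (`block_length_s` per block;
#'   epoch overlaps are not double-counted).
#' @export
grid_scored_seconds <- function(grid) {
  stopifnot(inherits(grid, "epoch_grid"))
  n_blocks <- length(unique(grid$block))
  n_blocks * attr(grid, "block_length_s")
}

# end of the last block (recording-time seconds)
grid_end_s <- function(grid) {
  if (nrow(grid) == 0) return(0)
  max(grid$end_s)
}

# total samples in the rasterized track spanning [0, grid_end)
grid_n_samples <- function(grid) {
  round(grid_end_s(grid) * attr(grid, "fs"))
}

# sample index range (1-based, inclusive) covered by [from_s, to_s)
sample_range <- function(from_s, to_s, fs) {
  i0 <- round(from_s * fs) + 1L
  i1 <- round(to_s * fs)
  c(i0, i1)
}
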