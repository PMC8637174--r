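#' Scalp montage for the probe-in-task recordings
#'
#' A montage holds the ordered scalp channel labels, their 2-D head-plane
#' coordinates on the unit disc (nose up, +y anterior, +x right), and the
#' two mastoid reference labels. The default montage is the 60-channel
#' extended 10-10 layout used throughout the package; reduced montages
#' (subsets of the same layout) are supported everywhere so that analyses
#' can be run at smaller problem sizes.
#'
#' @param channel_labels character vector of unique scalp labels drawn from
#'   the extended 10-10 system (default: the full 60-channel set).
#' @param reference_labels two mastoid labels, disjoint from the scalp set.
#' @return An object of class `mwl_montage` with elements `channel_labels`,
#'   `channel_positions` (n x 2 matrix, rows named by label), and
#'   `reference_labels`.
#' @examples
#' m <- default_montage()
#' nrow(m$channel_positions)  # 60
#' @export
default_montage <- function(channel_labels = montage_1010_labels(),
                            reference_labels = c("M1", "M2")) {
  channel_labels <- as.character(channel_labels)
  if (anyDuplicated(channel_labels))
    stop("montage channel labels must be unique")
  if (length(reference_labels) != 2L)
    stop("exactly two mastoid reference labels are required")
  if (any(reference_labels %in% channel_labels))
    stop("mastoid labels must be disjoint from scalp labels")
  pos <- montage_1010_positions()
  missing <- setdiff(channel_labels, rownames(pos))
  if (length(missing))
    stop("unknown 10-10 labels: ", paste(missing, collapse = ", "))
  structure(
    list(channel_labels = channel_labels,
         channel_positions = pos[channel_labels, , drop = FALSE],
         reference_labels = as.character(reference_labels)),
    class = "mwl_montage")
}

#' The 60 scalp labels of the extended 10-10 layout
#' @return character vector of length 60, anterior to posterior.
#' @export
montage_1010_labels <- function() {
  c("Fp1", "Fpz", "Fp2",
    "AF3", "AF4",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "O1", "Oz", "O2")
}

# Head-plane coordinates: each sagittal row gets a fixed y; the lateral
# position is derived from the numeric suffix of the label (odd = left,
# even = right, z = midline), scaled to stay inside the unit disc.
montage_1010_positions <- function() {
  labels <- montage_1010_labels()
  row_y <- c(Fp = 0.85, AF = 0.65, F = 0.45, FC = 0.22, C = 0,
             CP = -0.22, P = -0.45, PO = -0.65, O = -0.85)
  # temporal labels share the C/CP/F rows
  row_of <- function(lab) {
    stem <- sub("[0-9z]+$", "", lab)
    switch(stem,
           Fp = "Fp", AF = "AF", F = "F", FT = "FC", FC = "FC",
           T = "C", C = "C", TP = "CP", CP = "CP", P = "P",
           PO = "PO", O = "O",
           stop("unknown label stem: ", stem))
  }
  pos <- t(vapply(labels, function(lab) {
    y <- row_y[[row_of(lab)]]
    if (grepl("z$", lab)) {
      x <- 0
    } else {
      d <- as.integer(sub("^[A-Za-z]+", "", lab))
      idx <- ceiling(d / 2)          # 1,2 -> 1 ... 7,8 -> 4
      sgn <- if (d %% 2L == 1L) -1 else 1
      w <- 0.92 * sqrt(max(1 - y^2, 0.05))
      x <- sgn * idx / 4 * w
    }
    c(x = x, y = y)
  }, numeric(2)))
  rownames(pos) <- labels
  pos
}

#' Reduced montages for small problem sizes
#'
#' Convenience subsets of the 10-10 layout that keep frontal, central,
#' parietal and occipital coverage, used for fast simulations and tests.
#'
#' @param n number of scalp channels: one of 4, 8, 16, or 60.
#' @return an `mwl_montage`.
#' @export
small_montage <- function(n = 16) {
  labels <- switch(as.character(n),
    "4"  = c("Fz", "Cz", "Pz", "Oz"),
    "8"  = c("Fz", "FCz", "Cz", "Pz", "F3", "F4", "P3", "P4"),
    "16" = c("Fp1", "Fp2", "F3", "Fz", "F4", "FCz", "T7", "C3", "Cz",
             "C4", "T8", "P3", "Pz", "P4", "POz", "Oz"),
    "60" = montage_1010_labels(),
    stop("supported reduced sizes are 4, 8, 16, 60"))
  default_montage(channel_labels = labels)
}

#' Gaussian spatial gain over a montage
#'
#' Per-channel gain in \[0, 1\] from a circular Gaussian on the head plane,
#' used to build component and band topographies.
#'
#' @param montage an `mwl_montage`.
#' @param center length-2 numeric (x, y) on the head plane.
#' @param width Gaussian spatial SD (head-plane units).
#' @return named numeric vector of gains, one per scalp channel.
#' @export
gaussian_topography <- function(montage, center = c(0, 0.3), width = 0.5) {
  stopifnot(inherits(montage, "mwl_montage"), width > 0)
  pos <- montage$channel_positions
  d2 <- (pos[, 1] - center[1])^2 + (pos[, 2] - center[2])^2
  g <- exp(-d2 / (2 * width^2))
  names(g) <- montage$channel_labels
  g
}

n_channels <- function(montage) length(montage$channel_labels)

#' @export
print.mwl_montage <- function(x, ...) {
  cat(sprintf("<mwl_montage> %d scalp channels, references: %s\n",
              n_channels(x), paste(x$reference_labels, collapse = ", ")))
  invisible(x)
}
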