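#' Default 61-channel montage
#'
#' A synthetic 2-D projection of a 61-channel 10-10 EEG montage (channel
#' name, projected x/y, scalp row).  Distances on this projection are used
#' only to order channels for neighborhood construction; no 3-D geodesics
#' are computed.
#'
#' @param file TSV with columns `channel`, `x`, `y`, `row`.
#' @return data frame of 61 channels.
#' @export
default_montage <- function(file = system.file("extdata",
                                               "montage_61_synthetic.tsv",
                                               package = "grasprsa")) {
  m <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("channel", "x", "y", "row")
  if (!all(need %in% names(m))) stopf("montage needs columns %s",
                                      paste(need, collapse = ", "))
  if (anyDuplicated(m$channel)) stopf("montage has duplicated channels")
  m
}

# Serpentine traversal of the montage: anterior to posterior rows, within a
# row from one periphery across the midline to the other, alternating
# direction so consecutive path members stay spatially adjacent.
channel_path <- function(montage) {
  rows <- sort(unique(montage$row))
  path <- character(0)
  for (i in seq_along(rows)) {
    ch <- montage[montage$row == rows[i], ]
    ch <- ch[order(ch$x), ]
    ord <- ch$channel
    if (i %% 2 == 0) ord <- rev(ord)
    path <- c(path, ord)
  }
  path
}

#' Frequency-band neighborhoods for the searchlight
#'
#' Sliding sets of `members` consecutive frequency bins in which each
#' neighborhood shares exactly `shared` bins with the next one
#' (stride = members - shared).  On the default 0.5-Hz grid each
#' 5-bin neighborhood spans a 2-Hz band and the 80-bin grid yields 26
#' neighborhoods.
#'
#' @param n_bins number of frequency bins on the analysis grid.
#' @param members neighborhood size (default 5).
#' @param shared bins shared by consecutive neighborhoods (default 2).
#' @return list of integer vectors of bin indices.
#' @export
build_frequency_neighborhoods <- function(n_bins, members = 5, shared = 2) {
  if (members < 2 || shared < 0 || shared >= members)
    stopf("need 0 <= shared < members")
  if (n_bins < members)
    stopf("frequency grid (%d bins) shorter than one neighborhood (%d)",
          n_bins, members)
  stride <- members - shared
  n_nb <- floor((n_bins - members) / stride) + 1
  lapply(seq_len(n_nb), function(i) {
    start <- (i - 1) * stride + 1
    seq.int(start, start + members - 1)
  })
}

#' Channel neighborhoods for the searchlight
#'
#' Builds `n_centroids` channel neighborhoods of `members` channels each
#' from an ordered serpentine traversal of the montage
#' (anterior-to-posterior, periphery-to-midline rows).  Neighborhoods are
#' cyclic windows along the traversal with stride `members - shared`, so
#' every pair of consecutive neighborhoods shares exactly `shared`
#' channels.  The centroid is the middle channel of each window.
#'
#' @param montage montage data frame, see [default_montage()].
#' @param n_centroids number of neighborhoods (default 31).
#' @param members neighborhood size (default 5).
#' @param shared channels shared by consecutive neighborhoods (default 2).
#' @return named list (centroid channel name) of character vectors.
#' @export
build_channel_neighborhoods <- function(montage = default_montage(),
                                        n_centroids = 31, members = 5,
                                        shared = 2) {
  path <- channel_path(montage)
  n <- length(path)
  if (n < members) stopf("montage has %d channels, need at least %d", n, members)
  stride <- members - shared
  if (n_centroids * stride > n * members)
    stopf("cannot place %d neighborhoods on %d channels", n_centroids, n)
  nbs <- lapply(seq_len(n_centroids), function(i) {
    idx <- (((i - 1) * stride) + seq_len(members) - 1) %% n + 1
    path[idx]
  })
  starts <- vapply(nbs, `[`, character(1), 1)
  if (anyDuplicated(starts))
    stopf("neighborhood construction produced duplicate windows")
  names(nbs) <- vapply(nbs, `[`, character(1), (members + 1) %/% 2)
  nbs
}

#' ERD/S analysis frequency grid
#'
#' The 0.5-Hz-step grid over the analyzed 0.1-40 Hz band.  Bin centers
#' start at 0.5 Hz (the 0.1-Hz band edge lies below the first 0.5-Hz bin
#' center), giving 80 bins: 0.5, 1.0, ..., 40 Hz.
#'
#' @return numeric vector of bin center frequencies (Hz).
#' @export
erds_freq_grid <- function() seq(0.5, 40, by = 0.5)

#' Assemble and validate a searchlight layout
#'
#' Combines channel neighborhoods and frequency neighborhoods into the
#' layout scanned by the searchlight.  The default layout has 31 channel
#' neighborhoods over 61 channels and 26 frequency neighborhoods over the
#' 80-bin 0.5-Hz grid, i.e. 806 searchlight cells.
#'
#' @param montage montage data frame.
#' @param freqs frequency grid (Hz).
#' @param n_centroids number of channel neighborhoods.
#' @param members,shared neighborhood size and overlap (both spaces).
#' @return object of class `searchlight_layout` with elements
#'   `channel_neighborhoods`, `frequency_neighborhoods`, `freqs`,
#'   `channels`.
#' @export
searchlight_layout <- function(montage = default_montage(),
                               freqs = erds_freq_grid(),
                               n_centroids = 31, members = 5, shared = 2) {
  layout <- structure(list(
    channel_neighborhoods = build_channel_neighborhoods(
      montage, n_centroids, members, shared),
    frequency_neighborhoods = build_frequency_neighborhoods(
      length(freqs), members, shared),
    freqs = freqs,
    channels = montage$channel,
    members = members, shared = shared), class = "searchlight_layout")
  validate_layout(layout)
  layout
}

#' Validate a searchlight layout
#'
#' Enforces the structural invariants: every neighborhood (in channel and
#' frequency space) has exactly `members` members, consecutive
#' neighborhoods share exactly `shared` members, all channels exist in the
#' montage channel set and all bin indices lie on the grid.  Any layout
#' violating these is rejected, whether shipped or user supplied.
#'
#' @param layout a `searchlight_layout`.
#' @param channels optional channel inventory to validate against.
#' @return the layout, invisibly; errors on violation.
#' @export
validate_layout <- function(layout, channels = layout$channels) {
  m <- layout$members %||% 5
  s <- layout$shared %||% 2
  cnb <- layout$channel_neighborhoods
  fnb <- layout$frequency_neighborhoods
  if (!length(cnb) || !length(fnb)) stopf("layout has empty neighborhood lists")
  bad <- vapply(cnb, function(x) length(x) != m || anyDuplicated(x) > 0,
                logical(1))
  if (any(bad)) stopf("channel neighborhood(s) %s do not have %d distinct members",
                      paste(which(bad), collapse = ","), m)
  unknown <- setdiff(unique(unlist(cnb)), channels)
  if (length(unknown))
    stopf("layout channel(s) absent from montage: %s",
          paste(unknown, collapse = ", "))
  if (length(cnb) > 1) {
    ov <- vapply(seq_len(length(cnb) - 1), function(i)
      length(intersect(cnb[[i]], cnb[[i + 1]])), integer(1))
    if (any(ov != s))
      stopf("consecutive channel neighborhoods must share exactly %d members", s)
  }
  bad <- vapply(fnb, function(x) length(x) != m || anyDuplicated(x) > 0 ||
                  any(x < 1) || any(x > length(layout$freqs)), logical(1))
  if (any(bad)) stopf("frequency neighborhood(s) %s invalid",
                      paste(which(bad), collapse = ","))
  if (length(fnb) > 1) {
    ov <- vapply(seq_len(length(fnb) - 1), function(i)
      length(intersect(fnb[[i]], fnb[[i + 1]])), integer(1))
    if (any(ov != s))
      stopf("consecutive frequency neighborhoods must share exactly %d members", s)
  }
  invisible(layout)
}

#' @export
print.searchlight_layout <- function(x, ...) {
  cat(sprintf("Searchlight layout: %d channel x %d frequency neighborhoods (%d cells)\n",
              length(x$channel_neighborhoods), length(x$frequency_neighborhoods),
              length(x$channel_neighborhoods) * length(x$frequency_neighborhoods)))
  cat(sprintf("Frequency grid: %g-%g Hz, %d bins\n", min(x$freqs), max(x$freqs),
              length(x$freqs)))
  invisible(x)
}

#' Extract a searchlight pattern vector from an ERD/S map
#'
#' Concatenates the ERD/S values of one searchlight cell (5 channels x 5
#' frequency bins) over one 500-ms window into a vector, in fixed order:
#' channel index varies fastest, then frequency bin, then time sample.
#' Patterns extracted with the same neighbor ordering are comparable under
#' any correlation distance.
#'
#' @param erds ERD/S array, channels x frequency bins x time, with channel
#'   dimnames.
#' @param channel_nb character vector of neighborhood channel names.
#' @param freq_nb integer vector of frequency-bin indices.
#' @param window integer vector of time-sample indices into the third
#'   dimension (e.g. one of three consecutive 50-sample windows at 100 Hz).
#' @return numeric pattern vector of length
#'   `length(channel_nb) * length(freq_nb) * length(window)`; attribute
#'   `zero_variance` flags a constant pattern.
#' @export
extract_pattern <- function(erds, channel_nb, freq_nb, window) {
  ch_names <- dimnames(erds)[[1]]
  if (is.null(ch_names)) stopf("erds array must carry channel dimnames")
  idx <- match(channel_nb, ch_names)
  if (anyNA(idx)) stopf("channel(s) not in ERD/S map: %s",
                        paste(channel_nb[is.na(idx)], collapse = ", "))
  if (any(freq_nb < 1 | freq_nb > dim(erds)[2]))
    stopf("frequency bin index out of range")
  if (any(window < 1 | window > dim(erds)[3]))
    stopf("window exceeds available samples (have %d)", dim(erds)[3])
  v <- as.vector(erds[idx, freq_nb, window, drop = FALSE])
  attr(v, "zero_variance") <- isTRUE(sd(v) == 0)
  v
}
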