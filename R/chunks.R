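# A "scan set" is a per-flower list:
#   list(flower_id, species, syndrome, angles, planes = list(azimuth = irs,
#        elevation = irs))
# built by scan_set() below; chunks index into it by (plane, angle row).

#' Bundle simulated scans of a flower set for the classifier
#'
#' Simulates (or accepts) both scan planes for every flower and packages
#' them, together with the species labels, as the unit the chunking and
#' training functions consume.
#'
#' @param flowers flower table from [sample_flowers()].
#' @param truth an [acoustic_truth()].
#' @param cfg a [sim_config()].
#' @param seed seed for the flower-level TS residuals.
#' @return named list (by flower id) of per-flower scan entries.
#' @export
scan_set <- function(flowers, truth = acoustic_truth(), cfg = sim_config(),
                     seed = cfg$seed) {
  eps <- with_seed(seed, rnorm(nrow(flowers), sd = truth$noise_sd_db))
  ts_true <- expected_ts(flowers, truth) + eps
  out <- lapply(seq_len(nrow(flowers)), function(i) {
    fl <- flowers[i, ]
    planes <- lapply(c(azimuth = "azimuth", elevation = "elevation"),
                     function(pl) simulate_scan(fl, plane = pl,
                                                truth = truth, cfg = cfg,
                                                ts_db = ts_true[i])$irs)
    list(flower_id = fl$flower_id, species = fl$species,
         syndrome = fl$syndrome, angles = sim_angles(cfg), planes = planes)
  })
  names(out) <- flowers$flower_id
  out
}

.chunk <- function(entry, k, scheme, rows) {
  structure(list(flower_id = entry$flower_id, species = entry$species,
                 syndrome = entry$syndrome, k = k, scheme = scheme,
                 rows = rows),  # data.frame(plane, angle_idx)
            class = "echo_chunk")
}

#' Random echo chunks for one flower
#'
#' Pools the impulse responses of both planes, shuffles them along the angle
#' axis, and partitions the shuffled order into consecutive groups of `k`
#' echoes; a final remainder smaller than `k` is dropped. Emulates a bat
#' receiving echoes from scattered directions during approach.
#'
#' @param entry one element of a [scan_set()].
#' @param k echoes per chunk (1, 3, 5, 7 or 10 in the standard design).
#' @param seed integer seed.
#' @return list of `echo_chunk` objects (each holds plane/angle indices, not
#'   waveforms; spectrograms are computed on demand during training).
#' @export
chunk_random <- function(entry, k, seed = 1L) {
  pool <- do.call(rbind, lapply(names(entry$planes), function(pl)
    data.frame(plane = pl, angle_idx = seq_len(nrow(entry$planes[[pl]])),
               stringsAsFactors = FALSE)))
  if (nrow(pool) < k) stopf("flower %s has %d echoes; need k = %d",
                            entry$flower_id, nrow(pool), k)
  ord <- with_seed(seed, sample.int(nrow(pool)))
  n_chunks <- nrow(pool) %/% k
  lapply(seq_len(n_chunks), function(i) {
    .chunk(entry, k, "random", pool[ord[((i - 1) * k + 1):(i * k)], ])
  })
}

#' Interval echo chunks for one flower
#'
#' Draws a random interval `n` between 2 and 8 and a random start angle and
#' takes every `n`th impulse response, within one plane's angular order,
#' until `k` echoes are collected (no wrap-around; the draw is repeated if
#' the run would leave the scan). Emulates a bat approaching along a narrow
#' trajectory, receiving echoes in succession from one direction - chunks
#' are less angularly diverse than random chunks. The number of chunks per
#' flower is matched to what [chunk_random()] would produce, for a fair
#' comparison.
#'
#' @inheritParams chunk_random
#' @param intervals admissible angular strides.
#' @return list of `echo_chunk` objects.
#' @export
chunk_interval <- function(entry, k, seed = 1L,
                           intervals = 2:8) {
  n_angles <- length(entry$angles)
  if (!any((k - 1) * intervals + 1 <= n_angles))
    stopf("k = %d cannot fit in a %d-angle scan at any interval", k,
          n_angles)
  total <- sum(vapply(entry$planes, nrow, integer(1)))
  n_chunks <- total %/% k
  planes <- names(entry$planes)
  with_seed(seed, {
    lapply(seq_len(n_chunks), function(i) {
      repeat {
        pl <- planes[sample.int(length(planes), 1)]
        nn <- sample(intervals, 1)
        span <- (k - 1) * nn
        if (span + 1 > n_angles) next
        start <- sample.int(n_angles - span, 1)
        rows <- data.frame(plane = pl,
                           angle_idx = seq(start, by = nn,
                                           length.out = k),
                           stringsAsFactors = FALSE)
        return(.chunk(entry, k, "interval", rows))
      }
    })
  })
}

#' Stratified train / validation / test split by flower
#'
#' Assigns whole flowers of every species to the train, validation and test
#' subsets at random (default 8 / 2 / 2 per species, leftover flowers
#' unused), so no flower contributes echoes to more than one subset and
#' classification performance is not inflated by within-flower similarity.
#'
#' @param flowers flower table with `flower_id` and `species`.
#' @param counts named or positional integer vector (train, val, test).
#' @param seed integer seed.
#' @return list with character vectors `train`, `validation`, `test` of
#'   flower ids.
#' @export
split_by_flower <- function(flowers, counts = c(train = 8L, validation = 2L,
                                                test = 2L), seed = 1L) {
  counts <- as.integer(counts)
  need <- sum(counts)
  with_seed(seed, {
    parts <- list(train = character(), validation = character(),
                  test = character())
    for (sp in unique(flowers$species)) {
      ids <- flowers$flower_id[flowers$species == sp]
      if (length(ids) < need)
        stopf("species %s has %d flowers; need %d", sp, length(ids), need)
      ids <- sample(ids)
      parts$train <- c(parts$train, ids[seq_len(counts[1])])
      parts$validation <- c(parts$validation,
                            ids[counts[1] + seq_len(counts[2])])
      parts$test <- c(parts$test,
                      ids[counts[1] + counts[2] + seq_len(counts[3])])
    }
    parts
  })
}

#' Build chunks for a list of flowers
#'
#' @param scans a [scan_set()].
#' @param ids flower ids to include.
#' @param k echoes per chunk.
#' @param scheme `"random"` or `"interval"`.
#' @param seed integer seed (advanced per flower deterministically).
#' @param max_chunks_per_flower optional cap on chunks taken per flower
#'   (applied identically to both schemes; chunk order is already random).
#' @return flat list of `echo_chunk` objects.
#' @export
build_chunks <- function(scans, ids, k, scheme = c("random", "interval"),
                         seed = 1L, max_chunks_per_flower = Inf) {
  scheme <- match.arg(scheme)
  fun <- if (scheme == "random") chunk_random else chunk_interval
  out <- list()
  for (j in seq_along(ids)) {
    ch <- fun(scans[[ids[j]]], k, seed = seed + j)
    if (length(ch) > max_chunks_per_flower)
      ch <- ch[seq_len(max_chunks_per_flower)]
    out <- c(out, ch)
  }
  out
}

#' Mean pairwise angular spread of chunks
#'
#' Diagnostic used to verify that interval chunks are less angularly diverse
#' than random chunks: the mean over chunks of the mean absolute pairwise
#' difference of the echo angles within a chunk.
#'
#' @param chunks list of `echo_chunk` objects.
#' @param angles the scan angle grid (degrees).
#' @return scalar, degrees.
#' @export
chunk_angle_spread <- function(chunks, angles) {
  mean(vapply(chunks, function(ch) {
    a <- angles[ch$rows$angle_idx]
    if (length(a) < 2) return(0)
    mean(abs(outer(a, a, `-`))[lower.tri(diag(length(a)))])
  }, numeric(1)))
}
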