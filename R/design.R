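#' Build a block design for the why/how inference task
#'
#' Lays out a block-design timeline crossing inference level (why, how) with
#' target category (faces, hands, optionally nonsocial). Within each target
#' category the order of why and how blocks is counterbalanced (alternating
#' AB/BA pairs, pair order shuffled under the seed); block onsets are then
#' fixed given the seed. Each block is a run of speeded trials; the block
#' window spans the onset of its first target image to the offset of its
#' final image.
#'
#' @param n_blocks_per_condition Blocks per inference-by-target cell (>= 1).
#' @param stimuli_per_block Trials per block (>= 1).
#' @param tr Repetition time in seconds (> 0).
#' @param targets Target categories; `"nonsocial"` may be appended for the
#'   task variants that include the nonsocial control condition.
#' @param soa Stimulus onset asynchrony within a block (seconds).
#' @param response_window Maximum time to respond to each image (seconds).
#' @param cue_dur Duration of the verbal cue preceding each block (seconds).
#' @param rest_dur Rest after each block (seconds).
#' @param initial_rest Lead-in rest (seconds).
#' @param seed Integer seed fixing the counterbalanced block order.
#' @return A `block_design` object: `$blocks` (one row per block: condition,
#'   inference, target, onset, offset), `$trials` (onset and response window,
#'   with block ids), `$tr`, `$n_volumes`.
#' @export
make_block_design <- function(n_blocks_per_condition = 4,
                              stimuli_per_block = 8,
                              tr = 1,
                              targets = c("faces", "hands"),
                              soa = 2.1,
                              response_window = 1.75,
                              cue_dur = 2,
                              rest_dur = 8,
                              initial_rest = 10,
                              seed = 1L) {
  if (n_blocks_per_condition < 1 || stimuli_per_block < 1)
    stop("block and stimulus counts must be >= 1")
  if (tr <= 0 || soa <= 0 || response_window <= 0)
    stop("tr, soa and response_window must be positive")
  targets <- match.arg(targets, c("faces", "hands", "nonsocial"),
                       several.ok = TRUE)
  set.seed(seed)

  # counterbalanced why/how order within each target category:
  # alternating AB / BA pairs, pair polarity shuffled
  order_by_target <- lapply(targets, function(tg) {
    pairs <- lapply(seq_len(n_blocks_per_condition), function(i) {
      if (stats::runif(1) < 0.5) c("why", "how") else c("how", "why")
    })
    unlist(pairs)
  })
  names(order_by_target) <- targets

  # interleave target categories round-robin
  n_per_target <- 2L * n_blocks_per_condition
  seq_rows <- list()
  for (i in seq_len(n_per_target))
    for (tg in targets)
      seq_rows[[length(seq_rows) + 1L]] <-
        data.frame(inference = order_by_target[[tg]][i], target = tg,
                   stringsAsFactors = FALSE)
  sequence <- do.call(rbind, seq_rows)

  block_dur <- (stimuli_per_block - 1) * soa + response_window
  blocks <- list(); trials <- list()
  t_cur <- initial_rest
  counter <- stats::setNames(rep(0L, length(targets) * 2L),
                             as.vector(outer(c("why", "how"), targets,
                                             paste, sep = "_")))
  for (b in seq_len(nrow(sequence))) {
    inf <- sequence$inference[b]; tg <- sequence$target[b]
    cond <- paste(inf, tg, sep = "_")
    counter[cond] <- counter[cond] + 1L
    t_cur <- t_cur + cue_dur
    onset <- t_cur
    offset <- onset + block_dur
    block_id <- sprintf("%s_b%d", cond, counter[cond])
    blocks[[b]] <- data.frame(block = block_id, condition = cond,
                              inference = inf, target = tg,
                              onset = onset, offset = offset,
                              stringsAsFactors = FALSE)
    trials[[b]] <- data.frame(block = block_id, condition = cond,
                              onset = onset + (seq_len(stimuli_per_block) - 1) * soa,
                              response_window = response_window,
                              stringsAsFactors = FALSE)
    t_cur <- offset + rest_dur
  }
  total_t <- t_cur + rest_dur
  design <- structure(list(
    blocks = do.call(rbind, blocks),
    trials = do.call(rbind, trials),
    targets = targets,
    n_blocks_per_condition = as.integer(n_blocks_per_condition),
    stimuli_per_block = as.integer(stimuli_per_block),
    tr = tr,
    n_volumes = as.integer(ceiling(total_t / tr)),
    seed = as.integer(seed)
  ), class = "block_design")
  validate_block_design(design)
  design
}

#' Validate a block design's structural invariants
#'
#' Checks that blocks are non-overlapping and inside the scan, every
#' condition has at least one block, every trial lies within its block and
#' response windows are positive. Invisibly returns the design; errors
#' otherwise.
#' @param design A `block_design`.
#' @export
validate_block_design <- function(design) {
  stopifnot(inherits(design, "block_design"))
  b <- design$blocks
  scan_end <- design$n_volumes * design$tr
  if (any(b$onset < 0) || any(b$offset > scan_end))
    stop("blocks must lie within [0, n_volumes * tr)")
  ord <- order(b$onset)
  if (any(b$onset[ord][-1] < b$offset[ord][-nrow(b)]))
    stop("blocks overlap")
  if (any(table(b$condition) < 1)) stop("every condition needs >= 1 block")
  tr_tab <- design$trials
  if (any(tr_tab$response_window <= 0)) stop("response window must be > 0")
  m <- match(tr_tab$block, b$block)
  if (any(tr_tab$onset < b$onset[m] - 1e-9) ||
      any(tr_tab$onset + tr_tab$response_window > b$offset[m] + 1e-9))
    stop("trials must lie within their block")
  invisible(design)
}

#' @export
print.block_design <- function(x, ...) {
  cat("Block design:", nrow(x$blocks), "blocks (",
      x$n_blocks_per_condition, "per condition ), targets:",
      paste(x$targets, collapse = ", "), "\n")
  cat("  ", x$stimuli_per_block, "stimuli/block; TR", x$tr, "s;",
      x$n_volumes, "volumes\n")
  invisible(x)
}
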