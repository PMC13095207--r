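#' Build a double-pass session design
#'
#' Lays out the trial table of a yes/no detection session with a double-pass
#' structure: each block presents a set of unique stimuli twice in identical
#' order. With the defaults (43 blocks of 140 trials, 70 unique stimuli per
#' block) each block consists of four runs of 35 trials: stimuli 1-35 on
#' trials 1-35, repeated in the same order on trials 36-70, then stimuli
#' 36-70 on trials 71-105, repeated on trials 106-140. Half of the unique
#' stimuli (rounded) carry a target; target status, side and the stimulus
#' RNG key are properties of the unique stimulus, so both passes are
#' pixel-identical.
#'
#' @param nBlocks number of blocks (default 43).
#' @param trialsPerBlock trials per block (default 140; must be even).
#' @param uniqueStimuli unique stimuli per block (default
#'   \code{trialsPerBlock / 2}).
#' @param pTarget probability that a unique stimulus contains the target
#'   (default 0.5; the target count per block is \code{round(uniqueStimuli *
#'   pTarget)}).
#' @param setSize stimuli per presentation run before it repeats (default 35,
#'   clamped to \code{uniqueStimuli}); consecutive runs alternate
#'   first-pass/second-pass to limit fatigue confounds.
#' @param contrast target Michelson/RMS contrast recorded in the table
#'   (default 0.15, a typical titrated level).
#' @param seed integer seed; stimulus RNG keys are derived from it.
#' @return data.frame with one row per trial and columns \code{block},
#'   \code{trial_in_block}, \code{stimulus_id}, \code{pass_index} (1 or 2),
#'   \code{target_present} (logical), \code{side} ("left"/"right"),
#'   \code{contrast}, \code{stim_seed}.
#' @examples
#' design <- makeSessionDesign(nBlocks = 2, seed = 1)
#' table(design$pass_index)
#' @export
makeSessionDesign <- function(nBlocks = 43L, trialsPerBlock = 140L,
                              uniqueStimuli = trialsPerBlock %/% 2L,
                              pTarget = 0.5, setSize = 35L,
                              contrast = 0.15, seed = 1L) {
  if (trialsPerBlock %% 2L != 0L)
    stop("invalid design: trialsPerBlock must be even (double-pass)")
  if (trialsPerBlock != 2L * uniqueStimuli)
    stop("invalid design: trialsPerBlock must equal 2 * uniqueStimuli")
  if (pTarget < 0 || pTarget > 1) stop("pTarget must be in [0, 1]")
  setSize <- min(as.integer(setSize), as.integer(uniqueStimuli))

  withLocalSeed(seed, {
    blocks <- lapply(seq_len(nBlocks), function(b) {
      u <- as.integer(uniqueStimuli)
      nTarget <- round(u * pTarget)
      present <- rep(FALSE, u)
      present[sample.int(u, nTarget)] <- TRUE
      side <- sample(c("left", "right"), u, replace = TRUE)
      stimSeed <- sample.int(2147483646L, u)
      ids <- sprintf("b%03d_s%03d", b, seq_len(u))

      # runs of `setSize` stimuli, each presented then repeated in order
      order1 <- integer(0)
      passIdx <- integer(0)
      start <- 1L
      while (start <= u) {
        run <- start:min(start + setSize - 1L, u)
        order1 <- c(order1, run, run)
        passIdx <- c(passIdx, rep(1L, length(run)), rep(2L, length(run)))
        start <- start + setSize
      }
      data.frame(
        block = b,
        trial_in_block = seq_len(trialsPerBlock),
        stimulus_id = ids[order1],
        pass_index = passIdx,
        target_present = present[order1],
        side = side[order1],
        contrast = contrast,
        stim_seed = stimSeed[order1],
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
  })
}

#' Write a trial table as CSV
#'
#' Serialises a trial table in the package's documented CSV schema
#' (participant, session, block, trial_in_block, stimulus_id, pass_index,
#' target_present, side, contrast, response, confidence). Missing behavioural
#' columns are written as NA.
#'
#' @param table trial table data.frame.
#' @param file output path.
#' @param participant,session identifiers recorded in the file.
#' @return invisibly, the written data.frame.
#' @export
writeTrialTable <- function(table, file, participant = 1L, session = 1L) {
  cols <- c("block", "trial_in_block", "stimulus_id", "pass_index",
            "target_present", "side", "contrast", "response", "confidence")
  for (cc in setdiff(cols, names(table))) table[[cc]] <- NA
  out <- cbind(participant = participant, session = session, table[cols])
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
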