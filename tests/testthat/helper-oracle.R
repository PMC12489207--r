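# Independent brute-force re-enactment of a transformed up-down track.
# Deliberately written as a flat transcript of the procedure (explicit local
# variables, no shared code with the package's update rule) so it can serve
# as an oracle for the staircase implementation.
oracle_staircase <- function(corrects, steps, budgets, initial,
                             floor = NA, floor_limit = 6L, n_down = 2L) {
  total <- sum(budgets)
  cuts <- cumsum(budgets)
  snr <- initial
  cc <- 0L
  last_move <- 0L     # 0 none, -1 down, +1 up
  revs <- 0L
  floor_hits <- 0L
  snrs <- numeric(0)
  rev_flags <- logical(0)
  phases <- integer(0)
  floored <- FALSE
  for (ok in corrects) {
    phase <- if (revs >= total) length(cuts) else which(revs < cuts)[1]
    snrs <- c(snrs, snr)
    phases <- c(phases, phase)
    this_rev <- FALSE
    if (ok && !is.na(floor) && isTRUE(all.equal(snr, floor))) {
      floor_hits <- floor_hits + 1L
      if (floor_hits >= floor_limit) {
        rev_flags <- c(rev_flags, FALSE)
        floored <- TRUE
        break
      }
    }
    move <- 0L
    if (ok) {
      cc <- cc + 1L
      if (cc >= n_down) { move <- -1L; cc <- 0L }
    } else {
      cc <- 0L
      move <- 1L
    }
    if (move != 0L) {
      new_snr <- snr + move * steps[phase]
      if (!is.na(floor)) new_snr <- max(new_snr, floor)
      if (last_move != 0L && move != last_move) {
        revs <- revs + 1L
        this_rev <- TRUE
      }
      last_move <- move
      snr <- new_snr
    }
    rev_flags <- c(rev_flags, this_rev)
    if (revs >= total) break
  }
  final_phase <- length(cuts)
  srt <- if (floored) floor else mean(snrs[phases == final_phase])
  list(snrs = snrs, reversals = revs, srt = srt, floored = floored,
       phases = phases, rev_flags = rev_flags, n_trials = length(snrs))
}

# drive the oracle with a response rule on the fly
oracle_run <- function(respond_fn, steps, budgets, initial,
                       floor = NA, floor_limit = 6L, max_trials = 200L) {
  # grow the correctness sequence one trial at a time by replaying prefixes
  corrects <- logical(0)
  repeat {
    res <- oracle_staircase(corrects, steps, budgets, initial, floor, floor_limit)
    done <- res$floored || res$reversals >= sum(budgets)
    if (done && res$n_trials == length(corrects)) return(res)
    if (length(corrects) >= max_trials) stop("oracle runaway")
    next_snr <- if (length(corrects) == 0L) initial else {
      r2 <- oracle_staircase(corrects, steps, budgets, initial, floor, floor_limit)
      # the SNR of the next presentation equals the state after all responses;
      # re-enact once more with a dummy appended to read it
      r3 <- oracle_staircase(c(corrects, TRUE), steps, budgets, initial,
                             floor, floor_limit)
      r3$snrs[length(corrects) + 1L]
    }
    corrects <- c(corrects, respond_fn(next_snr))
  }
}

# spreadsheet-style agreement oracle: every quantity from first principles
oracle_agreement <- function(a, b) {
  n <- length(a)
  d <- a - b
  bias <- sum(d) / n
  sdd <- sqrt(sum((d - bias)^2) / (n - 1))
  ma <- sum(a) / n; mb <- sum(b) / n
  r <- sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  rmse <- sqrt(sum(d^2) / n)
  list(bias = bias, sd = sdd, loa_halfwidth = 1.96 * sdd, r = r, rmse = rmse)
}
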