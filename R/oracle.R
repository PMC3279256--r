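# Reference inference by direct continuous-time simulation.
#
# Unlike run_inference(), which advances a discrete virtual clock over the
# merged multi-activity stream, this routine treats each activity in
# isolation and computes emission instants analytically (last qualifying
# beat + quantum), applying the four criteria literally to the activity's
# own beat subsequence. It exists as an independent check of the engine on
# small inputs; the two agree to within one clock tick whenever beat times
# and the quantum lie on the tick grid.

#' Brute-force reference implementation of activity inference
#'
#' @param beat_stream Merged beat data frame, nondecreasing in `t`
#'   (intended for small streams, up to a few hundred beats).
#' @param specs List of [activity_spec] objects.
#' @return Data frame with one row per inferred instance: `name`, `start_t`,
#'   `end_t`, `inferred_at`, `n_beats`, `satisfied_artifacts`, ordered by
#'   `(inferred_at, name)`.
#' @export
oracle_inference <- function(beat_stream, specs) {
  if (inherits(specs, "activity_spec")) specs <- list(specs)
  df <- as.data.frame(beat_stream)
  out <- list()

  for (sp in specs) {
    arts <- sp$criteria$artifact_id
    min_b <- stats::setNames(sp$criteria$min_beats, arts)
    wait_full <- sp$t_max * 60
    q <- sp$quantum * 60
    sub <- df[df$artifact_id %in% arts, , drop = FALSE]
    sub <- sub[order(sub$t, sub$artifact_id), , drop = FALSE]

    blank <- function() list(count = 0L, first = NA_real_, last = NA_real_,
                             sat = FALSE)
    st <- stats::setNames(lapply(arts, function(a) blank()), arts)

    flush <- function(upto) {
      repeat {
        satn <- names(st)[vapply(st, `[[`, logical(1), "sat")]
        if (length(satn) < sp$k_required) break
        t_last <- max(vapply(st[satn], `[[`, numeric(1), "last"))
        e <- t_last + q
        if (e >= upto) break
        t_first <- min(vapply(st[satn], `[[`, numeric(1), "first"))
        if (t_last - t_first <= sp$t_max * 60) {
          n_beats <- sum(vapply(st[satn], `[[`, integer(1), "count"))
          out[[length(out) + 1L]] <<- data.frame(
            name = sp$name, start_t = t_first, end_t = t_last,
            inferred_at = e, n_beats = n_beats,
            satisfied_artifacts = paste(sort(satn), collapse = ";"),
            stringsAsFactors = FALSE)
        }
        st <<- stats::setNames(lapply(arts, function(a) blank()), arts)
      }
    }

    for (i in seq_len(nrow(sub))) {
      t <- sub$t[[i]]
      flush(t)
      a <- sub$artifact_id[[i]]
      s <- st[[a]]
      if (s$count == 0L) {
        s <- list(count = 1L, first = t, last = t, sat = FALSE)
      } else if (s$sat || t <= s$last + wait_full) {
        s$count <- s$count + 1L
        s$last <- t
      } else {
        s <- list(count = 1L, first = t, last = t, sat = FALSE)
      }
      if (!s$sat && s$count >= min_b[[a]]) s$sat <- TRUE
      st[[a]] <- s
    }
    flush(Inf)
  }

  if (!length(out))
    return(data.frame(name = character(), start_t = numeric(),
                      end_t = numeric(), inferred_at = numeric(),
                      n_beats = integer(), satisfied_artifacts = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$inferred_at, res$name), , drop = FALSE]
  rownames(res) <- NULL
  res
}
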