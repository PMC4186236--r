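#' Write a trajectory log as JSON lines
#'
#' One JSON object per step with the step schema produced by [dac_step()].
#' Timestamps are never logged, so identical runs give byte-identical files.
#'
#' @param log list of step records.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(log, path) {
  lines <- vapply(log, function(rec) {
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory log
#' @param path JSON-lines file.
#' @return list of step records.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop("read_trajectory: parse error at line ", i, ": ",
                           conditionMessage(e))
                    })
    rec$levels <- as.numeric(unlist(rec$levels))
    out[[i]] <- rec
  }
  out
}

#' Write a metrics table as CSV
#'
#' Fixed column order (as given), floats at 9 significant digits, rows
#' stably sorted by \code{(seed, phase)} when those columns exist.
#'
#' @param table a data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_metrics <- function(table, path) {
  if (nrow(table) && all(c("seed", "phase") %in% names(table))) {
    table <- table[order(table$seed, table$phase), , drop = FALSE]
  }
  num <- vapply(table, is.double, TRUE)
  table[num] <- lapply(table[num], function(x) signif(x, 9))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a metrics table
#' @param path CSV file.
#' @return a data.frame.
#' @export
read_metrics <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize long-term memory (and chain matrix) to JSON
#'
#' @param ltm a [ltm_new()] object.
#' @param wm a [wm_new()] object (chain matrix and trigger values).
#' @param path optional output file.
#' @return JSON string, invisibly when written.
#' @export
write_ltm <- function(ltm, wm, path = NULL) {
  obj <- list(
    goals = ltm$goals,
    segments = if (ltm$n) {
      lapply(seq_len(ltm$n), function(i) {
        list(seq_id = ltm$seq_id[i], d = ltm$d[i], k = ltm$k[i],
             step = ltm$step[i], pos = c(ltm$px[i], ltm$py[i]),
             waypoint = ltm$wp[i, ], ego_turn = ltm$ego_turn[i],
             ego_speed = ltm$ego_speed[i], pred = ltm$pred[i, ])
      })
    } else list(),
    chain = if (length(wm$C)) apply(wm$C, 1, identity, simplify = FALSE) else list(),
    trigger = wm$c
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(as.character(js), path)
    return(invisible(js))
  }
  js
}
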