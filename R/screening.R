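# Screening of raw fix tables: gross-outlier removal, movement-spike removal,
# and interval thinning. All filters return subsequences of their input in
# time order and are idempotent.

new_screen_report <- function(n_input, removed) {
  list(n_input = n_input,
       n_removed = nrow(removed),
       n_output = n_input - nrow(removed),
       removed = removed)
}

empty_removed <- function() {
  data.frame(index = integer(0), animal_id = character(0),
             t = as.POSIXct(character(0), tz = "UTC"),
             reason = character(0), stringsAsFactors = FALSE)
}

#' Remove gross location outliers
#'
#' Iteratively removes fixes lying more than `threshold_km` from their
#' time-adjacent retained neighbours (both neighbours for interior fixes, the
#' single neighbour for endpoints). Removal is one fix at a time, worst first,
#' recomputing neighbour distances after each removal so that consecutive
#' blunders are handled.
#'
#' @param fixes Fix data.frame for one animal (columns animal_id, t, x, y),
#'   time-ordered.
#' @param threshold_km Distance threshold in kilometres (default 100).
#' @return A list with `fixes` (retained rows) and `report`.
#' @export
remove_gross_outliers <- function(fixes, threshold_km = 100) {
  if (is.null(fixes) || nrow(fixes) == 0) stopf("no fixes to screen")
  n <- nrow(fixes)
  keep <- rep(TRUE, n)
  removed_idx <- integer(0)
  repeat {
    idx <- which(keep)
    if (length(idx) < 2) break
    xs <- fixes$x[idx]; ys <- fixes$y[idx]
    step <- sqrt(diff(xs)^2 + diff(ys)^2) / 1000
    d_prev <- c(Inf, step)
    d_next <- c(step, Inf)
    score <- pmin(d_prev, d_next)   # distance to nearest adjacent neighbour
    far <- score > threshold_km
    if (!any(far)) break
    worst <- idx[which.max(ifelse(far, score, -Inf))]
    keep[worst] <- FALSE
    removed_idx <- c(removed_idx, worst)
  }
  removed_idx <- sort(removed_idx)
  removed <- if (length(removed_idx))
    data.frame(index = removed_idx, animal_id = fixes$animal_id[removed_idx],
               t = fixes$t[removed_idx], reason = "gross_outlier",
               stringsAsFactors = FALSE)
  else empty_removed()
  list(fixes = fixes[keep, , drop = FALSE], report = new_screen_report(n, removed))
}

#' Remove back-and-forth movement spikes
#'
#' A single pass in time order over triples of successive retained fixes: the
#' middle fix is removed when the triple forms an out-and-back pattern (bearing
#' reversal of at least `reversal_deg`) with both legs' implied speed above
#' `speed_threshold_kmh`.
#'
#' @param fixes Fix data.frame for one animal, time-ordered.
#' @param speed_threshold_kmh Leg-speed threshold in km/h (default 1.5).
#' @param reversal_deg Minimum bearing reversal, degrees (default 150).
#' @return A list with `fixes` and `report`.
#' @export
remove_spikes <- function(fixes, speed_threshold_kmh = 1.5, reversal_deg = 150) {
  n <- nrow(fixes)
  if (n < 3)
    return(list(fixes = fixes, report = new_screen_report(n, empty_removed())))
  tt <- as.numeric(fixes$t)
  keep <- rep(TRUE, n)
  prev <- 1L
  removed_idx <- integer(0)
  for (i in 2:(n - 1)) {
    nx <- i + 1L
    d1 <- dist_m(fixes$x[prev], fixes$y[prev], fixes$x[i], fixes$y[i])
    d2 <- dist_m(fixes$x[i], fixes$y[i], fixes$x[nx], fixes$y[nx])
    h1 <- (tt[i] - tt[prev]) / 3600
    h2 <- (tt[nx] - tt[i]) / 3600
    v1 <- d1 / 1000 / h1
    v2 <- d2 / 1000 / h2
    turn <- ang_diff_deg(heading_deg(fixes$x[i] - fixes$x[prev],
                                     fixes$y[i] - fixes$y[prev]),
                         heading_deg(fixes$x[nx] - fixes$x[i],
                                     fixes$y[nx] - fixes$y[i]))
    if (v1 > speed_threshold_kmh && v2 > speed_threshold_kmh &&
        turn >= reversal_deg) {
      keep[i] <- FALSE
      removed_idx <- c(removed_idx, i)
    } else {
      prev <- i
    }
  }
  removed <- if (length(removed_idx))
    data.frame(index = removed_idx, animal_id = fixes$animal_id[removed_idx],
               t = fixes$t[removed_idx], reason = "spike",
               stringsAsFactors = FALSE)
  else empty_removed()
  list(fixes = fixes[keep, , drop = FALSE], report = new_screen_report(n, removed))
}

#' Screen a fix table with both filters
#'
#' Applies [remove_gross_outliers()] then [remove_spikes()] per animal.
#'
#' @param fixes Fix data.frame, possibly multiple animals.
#' @param threshold_km Gross-outlier distance threshold, km.
#' @param speed_threshold_kmh Spike leg-speed threshold, km/h.
#' @param reversal_deg Spike bearing-reversal threshold, degrees.
#' @return A list with `fixes`, and `report` containing `n_input`,
#'   `n_gross_removed`, `n_spike_removed`, `n_output` and the `removed` table.
#' @export
screen_fixes <- function(fixes, threshold_km = 100, speed_threshold_kmh = 1.5,
                         reversal_deg = 150) {
  parts <- split(fixes, fixes$animal_id)
  out <- list(); rem <- list()
  for (a in names(parts)) {
    g <- remove_gross_outliers(parts[[a]], threshold_km)
    s <- remove_spikes(g$fixes, speed_threshold_kmh, reversal_deg)
    out[[a]] <- s$fixes
    rem[[a]] <- rbind(g$report$removed, s$report$removed)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  removed <- do.call(rbind, rem)
  rownames(removed) <- NULL
  list(fixes = res,
       report = list(n_input = nrow(fixes),
                     n_gross_removed = sum(removed$reason == "gross_outlier"),
                     n_spike_removed = sum(removed$reason == "spike"),
                     n_output = nrow(res),
                     removed = removed))
}

#' Thin fixes to a minimum time interval
#'
#' Greedy forward selection: the first fix is kept, then every fix whose gap
#' to the last kept fix is at least `min_gap_h` hours. On a regular 5-h
#' schedule the default retains 1 of every 10 locations.
#'
#' @param fixes Time-ordered fix data.frame (one or more animals; thinning is
#'   applied per animal).
#' @param min_gap_h Minimum gap in hours (default 47).
#' @return The retained subset, in input order.
#' @export
thin_by_interval <- function(fixes, min_gap_h = 47) {
  thin1 <- function(df) {
    n <- nrow(df)
    if (n <= 1) return(df)
    tt <- as.numeric(df$t)
    keep <- logical(n)
    keep[1] <- TRUE
    last <- tt[1]
    for (i in 2:n) {
      if ((tt[i] - last) / 3600 >= min_gap_h) {
        keep[i] <- TRUE
        last <- tt[i]
      }
    }
    df[keep, , drop = FALSE]
  }
  if (!"animal_id" %in% names(fixes) || length(unique(fixes$animal_id)) <= 1)
    return(thin1(fixes))
  res <- do.call(rbind, lapply(split(fixes, fixes$animal_id), thin1))
  rownames(res) <- NULL
  res
}
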