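#' Nearest reef to each fix
#'
#' Shortest Euclidean distance in two dimensions (x, y only; depth is
#' ignored). Ties are broken by lexicographic reef id.
#'
#' @param x,y fix coordinate vectors, m.
#' @param reefs data frame with \code{station_id}, \code{x}, \code{y}
#'   (reef rows of the station table).
#' @return data frame with \code{reef_id} and \code{distance} (m), one
#'   row per input fix.
#' @export
nearest_reef <- function(x, y, reefs) {
  if (is.null(reefs) || nrow(reefs) == 0L) stop("empty reef set")
  reefs <- reefs[order(reefs$station_id), , drop = FALSE]
  n <- length(x)
  reef_id <- character(n)
  distance <- numeric(n)
  # chunked n_fix x n_reef squared distances; ties.method = "first" picks
  # the lexicographically smallest id since reefs are sorted
  for (start in seq(1L, n, by = 100000L)) {
    idx <- start:min(n, start + 99999L)
    d2 <- outer(x[idx], reefs$x, "-")^2 + outer(y[idx], reefs$y, "-")^2
    j <- max.col(-d2, ties.method = "first")
    reef_id[idx] <- reefs$station_id[j]
    distance[idx] <- sqrt(d2[cbind(seq_along(idx), j)])
  }
  data.frame(reef_id = reef_id, distance = distance,
             stringsAsFactors = FALSE)
}

#' Detect reef visits along a track
#'
#' A fix is visiting its nearest reef iff its 2-D distance to that reef
#' is at most \code{visit_radius} (20 m by default, a conservative
#' threshold against attributing a fix to a neighbouring reef).
#' Maximal runs of consecutive fixes visiting the same reef collapse to
#' one visit event; off-reef fixes belong to no event.
#'
#' @param track a time-sorted, error-filtered \code{position_fixes}
#'   data frame (one or more fish).
#' @param reefs reef rows of the station table.
#' @param visit_radius m; default 20.
#' @return data frame of visit events: \code{fish_id}, \code{reef_id},
#'   \code{t_start}, \code{t_end}, \code{n_fixes}, time-sorted within
#'   fish.
#' @export
detect_visits <- function(track, reefs, visit_radius = 20) {
  out <- lapply(split(seq_len(nrow(track)), track$fish_id), function(idx) {
    tr <- track[idx, , drop = FALSE]
    nr <- nearest_reef(tr$x, tr$y, reefs)
    on <- nr$distance <= visit_radius
    # run id changes whenever visiting status or reef changes
    key <- ifelse(on, nr$reef_id, NA_character_)
    a <- key[-1L]; b <- key[-length(key)]
    chg <- (is.na(a) != is.na(b)) | (!is.na(a) & !is.na(b) & a != b)
    run <- cumsum(c(TRUE, chg))
    keep <- which(on)
    if (length(keep) == 0L) return(NULL)
    ev <- lapply(split(keep, run[keep]), function(ii) {
      data.frame(fish_id = tr$fish_id[1L], reef_id = key[ii[1L]],
                 t_start = tr$t[ii[1L]], t_end = tr$t[ii[length(ii)]],
                 n_fixes = length(ii), stringsAsFactors = FALSE)
    })
    do.call(rbind, ev)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(fish_id = character(), reef_id = character(),
                      t_start = as.POSIXct(character(), tz = "UTC"),
                      t_end = as.POSIXct(character(), tz = "UTC"),
                      n_fixes = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize reef switching for each fish
#'
#' A switch is a fish moving from one reef to another: a transition
#' between successive visit events with different reef ids. Leaving a
#' reef and returning to the same reef is not a switch (set
#' \code{count_same_reef_returns = TRUE} to count it). Average time per
#' reef is days tracked divided by the number of reef visits
#' (switches + 1); fish averaging under \code{super_switch_days} days
#' per reef are flagged as super-switchers.
#'
#' @param visits visit events from \code{\link{detect_visits}}.
#' @param days_tracked days each fish was tracked within the array:
#'   a single number (one fish) or a vector named by fish id.
#' @param count_same_reef_returns count a departure/return to the same
#'   reef as a switch? Default FALSE.
#' @param super_switch_days threshold (days per reef) below which a
#'   fish is classed a super-switcher; default 2.
#' @return data frame with one row per fish: \code{fish_id},
#'   \code{n_reefs_visited}, \code{n_switches}, \code{days_tracked},
#'   \code{avg_days_per_reef}, \code{super_switcher}.
#' @export
summarize_switching <- function(visits, days_tracked,
                                count_same_reef_returns = FALSE,
                                super_switch_days = 2) {
  ids <- if (length(days_tracked) > 1L || !is.null(names(days_tracked)))
    names(days_tracked) else unique(visits$fish_id)
  if (is.null(ids) || length(ids) == 0L) ids <- unique(visits$fish_id)
  if (is.null(names(days_tracked))) {
    if (length(ids) > 1L)
      stop("days_tracked must be named by fish id when several fish present")
    names(days_tracked) <- ids
  }
  rows <- lapply(ids, function(id) {
    dt <- unname(days_tracked[id])
    if (is.na(dt) || dt <= 0) stop("days_tracked must be > 0 for fish ", id)
    v <- visits[visits$fish_id == id, , drop = FALSE]
    v <- v[order(v$t_start), , drop = FALSE]
    r <- v$reef_id
    n_sw <- if (length(r) < 2L) 0L else if (count_same_reef_returns)
      length(r) - 1L else sum(r[-1L] != r[-length(r)])
    adr <- dt / (n_sw + 1)
    data.frame(fish_id = id, n_reefs_visited = length(unique(r)),
               n_switches = n_sw, days_tracked = dt,
               avg_days_per_reef = adr,
               super_switcher = adr < super_switch_days,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Height above bottom from sensor depth and bathymetry
#'
#' Height above bottom is the seabed depth at the cell containing the
#' fix (nearest-cell lookup) minus the transmitter pressure-sensor
#' depth. Negative values (fix apparently below the seabed, possible
#' with ~1 m position and sensor error) are retained but flagged.
#'
#' @param fixes \code{position_fixes} with a \code{depth} column.
#' @param bathy a \code{\link{bathy_grid}}.
#' @return data frame with \code{height_above_bottom} (m; NA when the
#'   fix falls outside the grid, in a NODATA cell or lacks depth) and
#'   \code{flag} in \code{"ok", "negative", "outside_grid", "no_depth"}.
#' @export
height_above_bottom <- function(fixes, bathy) {
  seabed <- bathy_depth_at(bathy, fixes$x, fixes$y)
  hab <- seabed - fixes$depth
  flag <- rep("ok", nrow(fixes))
  flag[is.na(fixes$depth)] <- "no_depth"
  flag[is.na(seabed)] <- "outside_grid"
  flag[!is.na(hab) & hab < 0] <- "negative"
  data.frame(height_above_bottom = hab, flag = flag,
             stringsAsFactors = FALSE)
}

#' Per-fix distance to the nearest reef
#'
#' Intended for the finer-scale analyses on 5-m-filtered tracks.
#'
#' @param track time-sorted \code{position_fixes}.
#' @param reefs reef rows of the station table.
#' @return data frame: \code{fish_id}, \code{t}, \code{reef_id},
#'   \code{distance} (m), one row per fix in time order within fish.
#' @export
distance_to_reef_series <- function(track, reefs) {
  nr <- nearest_reef(track$x, track$y, reefs)
  data.frame(fish_id = track$fish_id, t = track$t,
             reef_id = nr$reef_id, distance = nr$distance,
             stringsAsFactors = FALSE)
}
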