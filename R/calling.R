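# Positivity filters calling IgG-secreting cells from relocation traces.

# least-squares slope of y against 0-based index
.ls_slope <- function(y) {
  x <- seq_along(y) - 1
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Call IgG-secreting cells from relocation traces
#'
#' A droplet is called positive for IgG secretion when its red-channel
#' (anti-IgG) relocation trace satisfies all three filters: the trace
#' maximum exceeds `min_relocation` (1.2), the last-minus-first net
#' difference exceeds `net_difference` (0.025), and the least-squares slope
#' of relocation versus frame index is at least `slope` (0.004 relocation
#' units per frame interval). The "minimum relocation > 1.2" filter is a
#' floor on the achieved relocation: every trace starts at 1 by
#' construction, so it is the maximum that must clear the threshold.
#'
#' @param traces data.frame from [compute_relocation()] (columns droplet_id,
#'   frame, r_red, r_green), or a single [forward_kinetics()] trace.
#' @param cfg a [secretor_call_config()].
#' @return data.frame with one row per droplet: the three diagnostic
#'   statistics (`max_relocation`, `net_difference`, `slope`), `positive`,
#'   and a `failed_criteria` string.
#' @export
call_secretors <- function(traces, cfg = secretor_call_config()) {
  stopifnot(inherits(cfg, "secretor_call_config"))
  if (inherits(traces, "relocation_trace")) {
    traces <- data.frame(droplet_id = 1L, frame = seq_along(traces$times_min),
                         time_min = traces$times_min,
                         r_red = traces$r_red, r_green = traces$r_green)
  }
  col <- if (cfg$channel == "red") "r_red" else "r_green"
  sp <- split(traces[[col]], traces$droplet_id)
  if (any(lengths(sp) < 2)) {
    stop("relocation traces must have at least 2 frames")
  }
  ids <- names(sp)
  stat <- t(vapply(sp, function(r) {
    c(max(r), r[length(r)] - r[1], .ls_slope(r))
  }, numeric(3)))
  max_r <- stat[, 1]; net <- stat[, 2]; slp <- stat[, 3]
  pass <- cbind(max_r > cfg$min_relocation,
                net > cfg$net_difference,
                slp >= cfg$slope)
  crit <- c("min_relocation", "net_difference", "slope")
  failed <- vapply(seq_along(ids), function(i) {
    paste(crit[!pass[i, ]], collapse = ",")
  }, character(1))
  data.frame(droplet_id = utils::type.convert(ids, as.is = TRUE),
             max_relocation = max_r, net_difference = net, slope = slp,
             positive = rowSums(pass) == 3L,
             failed_criteria = failed, row.names = NULL)
}
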