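# Resistance of ecosystem functions to stress: the Orwin-Wardle index
# comparing stressed to control values of each function within each
# land use x diversity cell.

#' Orwin-Wardle resistance index
#'
#' `RS = 1 - 2|D0| / (|C0| + |D0|)` with `D0 = C0 - P0`, the
#' control-minus-stressed difference. Bounded in (-1, 1]; 1 means no change
#' under stress, values approach -1 as the stress-induced change dwarfs the
#' control level. `|C0|` in the denominator keeps the index defined for
#' functions whose control mean is legitimately negative (net N fluxes).
#'
#' @param c0 Control group mean(s).
#' @param p0 Stressed group mean(s).
#' @return Resistance value(s); `NA` with a warning where `C0 = P0 = 0`
#'   (0/0 undefined).
#' @export
resistance <- function(c0, p0) {
  d0 <- c0 - p0
  den <- abs(c0) + abs(d0)
  out <- 1 - 2 * abs(d0) / den
  undef <- !is.na(den) & den == 0
  if (any(undef)) {
    warning(sum(undef), " cell(s) with C0 = P0 = 0: resistance undefined (NA)",
            call. = FALSE)
    out[undef] <- NA_real_
  }
  out[!is.na(d0) & d0 == 0 & !undef] <- 1 # exact, no rounding residue
  out
}

#' Resistance of every function in every land use x diversity cell
#'
#' Computes C0 (control mean) and P0 (stressed mean) within each cell and
#' applies [resistance()] per function. `mode = "replicate"` instead pairs
#' each stressed replicate against the cell's control mean, giving
#' replicate-level RS values suitable for error bars and resampling.
#' Cells missing either group yield an `NA` row with a warning.
#'
#' @param funcs Function table from [function_table()].
#' @param meta Sample metadata.
#' @param functions Function columns to score (default all six).
#' @param mode `"cell_mean"` (one RS per cell, default) or `"replicate"`.
#' @return Data frame: `land_use`, `diversity_level`, `func`, (`replicate`,)
#'   `c0`, `p0`, `d0`, `resistance`, `n_control`, `n_stressed`.
#' @export
resistance_table <- function(funcs, meta, functions = ECOSYSTEM_FUNCTIONS,
                             mode = c("cell_mean", "replicate")) {
  mode <- match.arg(mode)
  df <- merge(funcs, meta, by = "sample_id")
  cells <- unique(df[, c("land_use", "diversity_level")])
  cells <- cells[order(cells$land_use, cells$diversity_level), ]
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    sub <- df[df$land_use == cells$land_use[ci] &
                df$diversity_level == cells$diversity_level[ci], ]
    ctrl <- sub[sub$stress == "control", ]
    strs <- sub[sub$stress == "stressed", ]
    if (!nrow(ctrl) || !nrow(strs)) {
      warning("cell ", cells$land_use[ci], " x ", cells$diversity_level[ci],
              " lacks a ", if (nrow(ctrl)) "stressed" else "control",
              " group: resistance NA", call. = FALSE)
    }
    for (fn in functions) {
      if (!nrow(ctrl) || !nrow(strs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          land_use = cells$land_use[ci],
          diversity_level = as.character(cells$diversity_level[ci]),
          func = fn, c0 = NA_real_, p0 = NA_real_, d0 = NA_real_,
          resistance = NA_real_, n_control = nrow(ctrl),
          n_stressed = nrow(strs), stringsAsFactors = FALSE)
        next
      }
      c0 <- mean(ctrl[[fn]])
      if (mode == "cell_mean") {
        p0 <- mean(strs[[fn]])
        rows[[length(rows) + 1L]] <- data.frame(
          land_use = cells$land_use[ci],
          diversity_level = as.character(cells$diversity_level[ci]),
          func = fn, c0 = c0, p0 = p0, d0 = c0 - p0,
          resistance = resistance(c0, p0),
          n_control = nrow(ctrl), n_stressed = nrow(strs),
          stringsAsFactors = FALSE)
      } else {
        for (ri in seq_len(nrow(strs))) {
          p0 <- strs[[fn]][ri]
          rows[[length(rows) + 1L]] <- data.frame(
            land_use = cells$land_use[ci],
            diversity_level = as.character(cells$diversity_level[ci]),
            func = fn, replicate = strs$replicate[ri],
            c0 = c0, p0 = p0, d0 = c0 - p0,
            resistance = resistance(c0, p0),
            n_control = nrow(ctrl), n_stressed = nrow(strs),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
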