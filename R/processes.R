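# Derived ecosystem-process rates and the multifunctionality index.
# Measured inputs (respiration, SIR, four enzyme rates, inorganic-N pools
# at two time points) come in through the process table; this module
# derives the metabolic quotient, net N rates, total enzyme activity, and
# the per-sample mean of z-scaled functions.

#' Metabolic quotient (qCO2): biomass-specific respiration
#'
#' Respiration per unit microbial biomass; higher values indicate lower
#' carbon-use efficiency. Non-positive biomass yields `NA` with a warning
#' rather than an error (a missing quotient, not an invalid table).
#'
#' @param respiration Basal respiration rate(s).
#' @param biomass Microbial biomass (same sample order).
#' @return `respiration / biomass`, `NA` where `biomass <= 0`.
#' @export
metabolic_quotient <- function(respiration, biomass) {
  out <- respiration / biomass
  bad <- !is.na(biomass) & biomass <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with non-positive biomass: qCO2 set to NA",
            call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Net N mineralization and nitrification rates
#'
#' Net N mineralization is the accumulation rate of total inorganic N
#' (NH4-N + NO3-N); net nitrification is the accumulation rate of NO3-N.
#' Either may be negative (net immobilization / NO3 consumption), which is
#' reported as-is.
#'
#' @param nh4_t0,no3_t0,nh4_t1,no3_t1 Inorganic-N pools (mg N kg-1) at the
#'   start and end of the incubation.
#' @param days Incubation interval (> 0, days).
#' @return List with vectors `n_mineralization` and `nitrification`
#'   (mg N kg-1 d-1).
#' @export
net_n_rates <- function(nh4_t0, no3_t0, nh4_t1, no3_t1, days) {
  if (any(days <= 0)) stop("incubation interval must be > 0 days", call. = FALSE)
  list(n_mineralization = ((nh4_t1 + no3_t1) - (nh4_t0 + no3_t0)) / days,
       nitrification = (no3_t1 - no3_t0) / days)
}

#' Total hydrolytic enzyme activity
#'
#' Sum of the four measured hydrolase rates (beta-glucosidase, leucine
#' aminopeptidase, N-acetyl-beta-glucosaminidase, acid phosphatase). `NA`
#' in any component propagates.
#'
#' @param bg,lap,nag,ap Enzyme rates (nmol g-1 h-1).
#' @return Summed rate.
#' @export
total_enzyme <- function(bg, lap, nag, ap) {
  bg + lap + nag + ap
}

#' Derive the six-function table from a process table
#'
#' @param proc Process table data frame (see [read_process_table()]) with
#'   columns `respiration`, `sir`, `biomass`, `enzyme_bg`, `enzyme_lap`,
#'   `enzyme_nag`, `enzyme_ap`, `nh4_t0`, `no3_t0`, `nh4_t1`, `no3_t1`,
#'   `interval_days`.
#' @return Data frame: `sample_id`, `c_mineralization`, `sir`, `qco2`,
#'   `total_enzyme`, `n_mineralization`, `nitrification`.
#' @export
function_table <- function(proc) {
  need <- c("respiration", "sir", "biomass", "enzyme_bg", "enzyme_lap",
            "enzyme_nag", "enzyme_ap", "nh4_t0", "no3_t0", "nh4_t1",
            "no3_t1", "interval_days")
  miss <- setdiff(need, names(proc))
  if (length(miss)) stop("process table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  nr <- net_n_rates(proc$nh4_t0, proc$no3_t0, proc$nh4_t1, proc$no3_t1,
                    proc$interval_days)
  data.frame(sample_id = proc$sample_id,
             c_mineralization = proc$respiration,
             sir = proc$sir,
             qco2 = metabolic_quotient(proc$respiration, proc$biomass),
             total_enzyme = total_enzyme(proc$enzyme_bg, proc$enzyme_lap,
                                         proc$enzyme_nag, proc$enzyme_ap),
             n_mineralization = nr$n_mineralization,
             nitrification = nr$nitrification,
             stringsAsFactors = FALSE)
}

ECOSYSTEM_FUNCTIONS <- c("c_mineralization", "sir", "qco2", "total_enzyme",
                         "n_mineralization", "nitrification")

#' Ecosystem multifunctionality: mean of z-scaled function rates
#'
#' Each selected function is z-scaled across samples ((x - mean)/sd, sample
#' sd by default) and the per-sample unweighted mean of z-scores is the
#' multifunctionality index. Unit-free by construction: affine rescaling of
#' any input function leaves the index unchanged.
#'
#' @param funcs Function table from [function_table()].
#' @param selected Function columns to include (default all six).
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return Data frame `sample_id`, `multifunctionality`; attribute `scaled`
#'   holds the z-score matrix.
#' @export
multifunctionality <- function(funcs, selected = ECOSYSTEM_FUNCTIONS,
                               sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (nrow(funcs) < 2) stop("need >= 2 samples to scale", call. = FALSE)
  miss <- setdiff(selected, names(funcs))
  if (length(miss)) stop("unknown function column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  z <- sapply(selected, function(fn) {
    x <- funcs[[fn]]
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    if (is.na(s) || s == 0) stop("function '", fn, "' has zero variance",
                                 call. = FALSE)
    (x - mean(x)) / s
  })
  out <- data.frame(sample_id = funcs$sample_id,
                    multifunctionality = rowMeans(z),
                    stringsAsFactors = FALSE)
  rownames(z) <- funcs$sample_id
  attr(out, "scaled") <- z
  out
}
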