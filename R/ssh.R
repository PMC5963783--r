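# Kinetic simulator of PCR-based suppression subtractive hybridization (SSH).
#
# Re-annealing of a melted cDNA pool follows second-order kinetics: abundant
# fragments meet their complements more often and re-anneal faster, which
# normalizes the pool; fragments present in the tester but depleted from the
# driver keep a larger adapter-ligated single-stranded fraction and are
# enriched. Species (AluI fragments) are treated as kinetically independent;
# cross-hybridization between distinct fragments is ignored.

#' Species pool for the SSH simulator
#'
#' @param species_id Character vector of fragment identifiers.
#' @param tester_conc,driver_conc Nonnegative concentration vectors (arbitrary
#'   units) for the tester (adapter-ligated) and driver (adapter-free) pools,
#'   indexed identically.
#' @return data.frame of class \code{species_pool}.
#' @export
species_pool <- function(species_id, tester_conc, driver_conc) {
  if (length(tester_conc) != length(species_id) ||
      length(driver_conc) != length(species_id)) {
    stop("species_id, tester_conc and driver_conc must have equal length",
         call. = FALSE)
  }
  if (any(tester_conc < 0) || any(driver_conc < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  out <- data.frame(species_id = as.character(species_id),
                    tester_conc = as.numeric(tester_conc),
                    driver_conc = as.numeric(driver_conc),
                    stringsAsFactors = FALSE)
  class(out) <- c("species_pool", "data.frame")
  out
}

#' Hybridization parameters
#'
#' The rate constant \code{rate_k} has no published value; its default is
#' chosen so that k*c*t1 is about 10 for the most abundant species of a unit
#' pool after 45 h, i.e. abundant shared fragments are strongly but not
#' completely removed. PEG acts purely as a rate multiplier (molecular
#' crowding raising the effective concentration) in the second hybridization.
#'
#' @param rate_k Second-order rate constant (per concentration unit per hour).
#' @param t1_hours Duration of the first hybridization (default 45 h).
#' @param t2_hours Duration of the second hybridization (default 24 h).
#' @param driver_excess Fold excess of driver over tester (default 60).
#' @param peg_rate_multiplier Rate multiplier applied in the second
#'   hybridization (>= 0; 0 models the no-PEG failure mode).
#' @return List of class \code{hybrid_params}.
#' @export
hybrid_params <- function(rate_k = 0.25, t1_hours = 45, t2_hours = 24,
                          driver_excess = 60, peg_rate_multiplier = 5) {
  if (rate_k <= 0) stop("rate_k must be > 0", call. = FALSE)
  if (t1_hours < 0 || t2_hours < 0) stop("times must be >= 0", call. = FALSE)
  if (driver_excess <= 0) stop("driver_excess must be > 0", call. = FALSE)
  if (peg_rate_multiplier < 0) {
    stop("peg_rate_multiplier must be >= 0", call. = FALSE)
  }
  structure(list(rate_k = rate_k, t1_hours = t1_hours, t2_hours = t2_hours,
                 driver_excess = driver_excess,
                 peg_rate_multiplier = peg_rate_multiplier),
            class = "hybrid_params")
}

#' First hybridization: second-order decay of single-stranded tester
#'
#' Adapter-A- and adapter-B-ligated tester aliquots are separately melted with
#' a \code{driver_excess}-fold excess of driver. For species i with total
#' complementary concentration \code{c_i = t_i + E * d_i}, both the sense and
#' antisense pools decay by the same factor, so the adapter-ligated
#' single-stranded tester follows the closed form
#' \code{s_i(t) = t_i / (1 + k * c_i * t)}.
#'
#' @param pool A [species_pool()].
#' @param params A [hybrid_params()].
#' @param tau Hybridization time in hours (defaults to \code{params$t1_hours}).
#' @return data.frame with columns \code{species_id}, \code{tester_conc},
#'   \code{total_conc}, \code{ss_A}, \code{ss_B} (remaining single-stranded
#'   adapter-ligated tester per reaction) and \code{annealed}.
#' @export
first_hybridization <- function(pool, params = hybrid_params(),
                                tau = params$t1_hours) {
  if (tau < 0) stop("hybridization time must be >= 0", call. = FALSE)
  cc <- pool$tester_conc + params$driver_excess * pool$driver_conc
  ss <- pool$tester_conc / (1 + params$rate_k * cc * tau)
  ss[pool$tester_conc == 0] <- 0
  data.frame(species_id = pool$species_id,
             tester_conc = pool$tester_conc,
             total_conc = cc,
             ss_A = ss, ss_B = ss,
             annealed = pool$tester_conc - ss,
             stringsAsFactors = FALSE)
}

# Closed-form product accumulation of the bimolecular reaction A + B -> AB
# with initial concentrations a and b and rate k: solves dx/dt = k(a-x)(b-x).
.duplex_closed_form <- function(a, b, k, t) {
  kt <- k * t
  out <- numeric(length(a))
  if (kt == 0) return(out)
  lo <- pmin(a, b); hi <- pmax(a, b)
  d <- hi - lo
  # near-symmetric case: series-stable equal-concentration limit
  sym <- d <= 1e-9 * pmax(hi, 1e-300)
  out[sym] <- (lo[sym]^2 * kt) / (1 + lo[sym] * kt)
  big <- !sym & lo > 0 & d * kt > 700  # exp overflow guard: limiting yield
  out[big] <- lo[big]
  ns <- !sym & lo > 0 & !big
  e <- exp(d[ns] * kt)
  out[ns] <- lo[ns] * hi[ns] * (e - 1) / (hi[ns] * e - lo[ns])
  out
}

#' Second hybridization: formation of A-B duplexes
#'
#' The adapter-A and adapter-B reactions are mixed and hybridization continues
#' for \code{t2_hours} at rate \code{k * peg_rate_multiplier}. Only hybrids
#' carrying both adapter A and adapter B are later amplifiable; their yield is
#' the bimolecular product of the two single-stranded pools and can never
#' exceed \code{min(ss_A, ss_B)} (mass conservation).
#'
#' @param hyb1 Output of [first_hybridization()] (columns \code{species_id},
#'   \code{ss_A}, \code{ss_B}).
#' @param params A [hybrid_params()].
#' @return data.frame with \code{species_id}, \code{ss_A}, \code{ss_B},
#'   \code{duplex_AB}.
#' @export
second_hybridization <- function(hyb1, params = hybrid_params()) {
  if (is.null(hyb1$ss_A) || is.null(hyb1$ss_B)) {
    stop("second_hybridization expects ss_A and ss_B columns", call. = FALSE)
  }
  k2 <- params$rate_k * params$peg_rate_multiplier
  dup <- .duplex_closed_form(hyb1$ss_A, hyb1$ss_B, k2, params$t2_hours)
  data.frame(species_id = hyb1$species_id,
             ss_A = hyb1$ss_A, ss_B = hyb1$ss_B, duplex_AB = dup,
             stringsAsFactors = FALSE)
}

#' Suppression PCR: amplification of A-B duplexes only
#'
#' Hybrids carrying two identical adapters fold intramolecularly and are not
#' amplified; amplification of A-B duplexes is exponential and
#' species-independent, so the final composition is the normalized duplex
#' yield.
#'
#' @param duplexes Output of [second_hybridization()] (or any data.frame with
#'   \code{species_id} and \code{duplex_AB}).
#' @param cycles Number of PCR cycles (composition-neutral; kept for the
#'   amplification bookkeeping).
#' @param efficiency Per-cycle amplification efficiency in (0, 1].
#' @return data.frame with \code{species_id}, \code{duplex_AB},
#'   \code{amplified}, \code{share} (summing to 1).
#' @export
suppression_pcr <- function(duplexes, cycles = 30L, efficiency = 0.95) {
  y <- duplexes$duplex_AB
  if (any(y < 0)) stop("duplex yields must be >= 0", call. = FALSE)
  if (sum(y) == 0) stop("empty subtracted library: no A-B duplexes to amplify",
                        call. = FALSE)
  amp <- y * (1 + efficiency)^cycles
  data.frame(species_id = duplexes$species_id,
             duplex_AB = y,
             amplified = amp,
             share = amp / sum(amp),
             stringsAsFactors = FALSE)
}

#' Run the full SSH simulation
#'
#' First hybridization, mixing with PEG, second hybridization, and
#' suppression PCR; returns the subtracted, normalized library composition.
#'
#' @param pool A [species_pool()].
#' @param params A [hybrid_params()].
#' @param cycles,efficiency Passed to [suppression_pcr()].
#' @return data.frame of class \code{ssh_result}: per species the input
#'   concentrations, single-stranded fractions, duplex yield and final
#'   \code{share}.
#' @examples
#' pool <- species_pool(c("shared", "repressed"), c(1, 1), c(1, 0.01))
#' run_ssh(pool)  # the repressed fragment ends up enriched
#' @export
run_ssh <- function(pool, params = hybrid_params(),
                    cycles = 30L, efficiency = 0.95) {
  h1 <- first_hybridization(pool, params)
  h2 <- second_hybridization(h1, params)
  pcr <- suppression_pcr(h2, cycles = cycles, efficiency = efficiency)
  out <- data.frame(species_id = pool$species_id,
                    tester_conc = pool$tester_conc,
                    driver_conc = pool$driver_conc,
                    ss_after_hyb1 = h1$ss_A,
                    duplex_AB = h2$duplex_AB,
                    share = pcr$share,
                    stringsAsFactors = FALSE)
  class(out) <- c("ssh_result", "data.frame")
  out
}

#' @export
print.ssh_result <- function(x, ...) {
  cat("SSH subtracted library:", nrow(x), "species\n")
  tester_share <- x$tester_conc / sum(x$tester_conc)
  enr <- x$share / tester_share
  top <- order(enr, decreasing = TRUE)[seq_len(min(5L, nrow(x)))]
  cat("most enriched over tester composition:\n")
  print(data.frame(species_id = x$species_id[top],
                   share = signif(x$share[top], 3),
                   enrichment = signif(enr[top], 3)), row.names = FALSE)
  invisible(x)
}
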