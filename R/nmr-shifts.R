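#' Published 1H/13C shift assignments for the anabasine / beta-cyclodextrin pair
#'
#' Assigned chemical shifts (ppm) of the anabasine guest and the
#' beta-cyclodextrin host, measured free and inside the 1:1 inclusion
#' complex, together with the displacement values as printed in the original
#' report. Guest sites 2-6 form the piperidine ring (site 2 resolves into
#' axial/equatorial proton rows, keyed `2-ax` / `2-eq`; its single carbon is
#' keyed `2`), sites 7-12 the pyridine ring. Host sites 1-6 are the
#' glucopyranose positions; H-3 and H-5 point into the cavity.
#'
#' @return A list with data.frames `free` and `complex` (columns `nucleus`,
#'   `molecule`, `site`, `delta_ppm`) and `printed` (the same keys plus
#'   `ddelta_printed`, the displacement as printed, which is not always the
#'   exact difference of the printed shift columns — see
#'   [check_printed_deltas()]).
#' @export
anabasine_bcd_shift_tables <- function() {
  # nucleus, molecule, site, delta_free, delta_complex, ddelta as printed
  rows <- rbind(
    c("1H",  "guest", "2-ax", 2.610,  2.610,   0),
    c("1H",  "guest", "2-eq", 2.991,  2.991,   0),
    c("1H",  "guest", "3",    1.882,  1.750,  -0.132),
    c("1H",  "guest", "4",    1.452,  1.442,  -0.010),
    c("1H",  "guest", "5",    1.471,  1.374,  -0.097),
    c("1H",  "guest", "6",    3.542,  3.556,   0.014),
    c("1H",  "guest", "8",    8.500,  8.490,  -0.010),
    c("1H",  "guest", "10",   8.380,  8.380,   0),
    c("1H",  "guest", "11",   7.263,  7.274,   0.011),
    c("1H",  "guest", "12",   7.680,  7.680,   0),
    c("13C", "guest", "2",    47.203, 47.163, -0.04),
    c("13C", "guest", "3",    25.973, 25.952, -0.021),
    c("13C", "guest", "4",    25.510, 25.480, -0.030),
    c("13C", "guest", "5",    35.245, 35.212, -0.033),
    c("13C", "guest", "6",    59.272, 59.335, -0.06),
    c("13C", "guest", "7",    141.602, 141.571, -0.031),
    c("13C", "guest", "8",    148.263, 148.285, 0.022),
    c("13C", "guest", "10",   148.620, 148.620, 0),
    c("13C", "guest", "11",   123.660, 123.702, 0.042),
    c("13C", "guest", "12",   134.522, 134.665, 0.143),
    c("1H",  "host",  "1",    4.773,  4.796,   0.023),
    c("1H",  "host",  "2",    3.270,  3.303,   0.033),
    c("1H",  "host",  "3",    3.490,  3.615,   0.123),
    c("1H",  "host",  "4",    3.302,  3.345,   0.042),
    c("1H",  "host",  "5",    3.450,  3.560,   0.110),
    c("1H",  "host",  "6",    3.572,  3.635,   0.063),
    c("13C", "host",  "1",    102.432, 102.667, 0.235),
    c("13C", "host",  "2",    72.875, 72.965,  0.091),
    c("13C", "host",  "3",    73.545, 73.685,  0.140),
    c("13C", "host",  "4",    82.005, 82.168,  0.163),
    c("13C", "host",  "5",    72.525, 72.658,  0.133),
    c("13C", "host",  "6",    60.402, 60.576,  0.174)
  )
  df <- data.frame(
    nucleus = rows[, 1], molecule = rows[, 2], site = rows[, 3],
    delta_free = as.numeric(rows[, 4]),
    delta_complex = as.numeric(rows[, 5]),
    ddelta_printed = as.numeric(rows[, 6]),
    stringsAsFactors = FALSE
  )
  key <- df[c("nucleus", "molecule", "site")]
  list(
    free = cbind(key, delta_ppm = df$delta_free),
    complex = cbind(key, delta_ppm = df$delta_complex),
    printed = cbind(key, ddelta_printed = df$ddelta_printed)
  )
}

check_shift_table <- function(tab, name) {
  req <- c("nucleus", "molecule", "site", "delta_ppm")
  if (!all(req %in% names(tab)))
    ck_stop(sprintf("%s table needs columns: %s", name, paste(req, collapse = ", ")),
            "ck_invalid_shift_table")
  if (any(!nzchar(tab$nucleus)) || any(!nzchar(as.character(tab$site))))
    ck_stop(sprintf("%s table has empty nucleus/site labels", name), "ck_invalid_shift_table")
  key <- paste(tab$nucleus, tab$molecule, tab$site)
  if (anyDuplicated(key))
    ck_stop(sprintf("duplicate keys in %s table: %s", name,
                    paste(unique(key[duplicated(key)]), collapse = "; ")),
            "ck_duplicate_sites")
  key
}

#' Chemical-shift displacements between free and complexed species
#'
#' Computes \eqn{\Delta\delta = \delta_{complex} - \delta_{free}} for every
#' (nucleus, molecule, site) key present in both tables. Positive values are
#' downfield shifts upon complexation. Keys present in only one table are
#' reported in the `unmatched` attribute, not silently dropped.
#'
#' @param free_table,complex_table data.frames with columns `nucleus`,
#'   `molecule`, `site`, `delta_ppm`.
#' @return A data.frame of class `shift_records` with columns `nucleus`,
#'   `molecule`, `site`, `delta_free`, `delta_complex`, `delta_delta` (exact
#'   arithmetic; round only for display), plus attribute `unmatched`.
#' @examples
#' tabs <- anabasine_bcd_shift_tables()
#' head(compute_delta(tabs$free, tabs$complex))
#' @export
compute_delta <- function(free_table, complex_table) {
  kf <- check_shift_table(free_table, "free")
  kc <- check_shift_table(complex_table, "complex")
  common <- intersect(kf, kc)
  if (!length(common)) ck_stop("no shared (nucleus, molecule, site) keys", "ck_empty_intersection")
  i <- match(common, kf); j <- match(common, kc)
  out <- data.frame(
    nucleus = free_table$nucleus[i],
    molecule = free_table$molecule[i],
    site = as.character(free_table$site[i]),
    delta_free = free_table$delta_ppm[i],
    delta_complex = complex_table$delta_ppm[j],
    stringsAsFactors = FALSE
  )
  out$delta_delta <- out$delta_complex - out$delta_free
  structure(out, class = c("shift_records", "data.frame"),
            unmatched = c(setdiff(kf, kc), setdiff(kc, kf)))
}

#' Audit printed displacement values against exact arithmetic
#'
#' Published shift tables occasionally print a displacement that is not the
#' exact difference of their own shift columns (typographic slips or sign
#' flips). This audit recomputes \eqn{\delta - \delta_0} per key, rounds it
#' to the printed precision, and flags cells where the printed value still
#' disagrees.
#'
#' @param records A [compute_delta()] result.
#' @param printed data.frame with key columns plus `ddelta_printed`.
#' @param digits Printed precision (decimal places). Default 3.
#' @return `records` with extra columns `ddelta_printed` and `consistent`;
#'   the inconsistent keys are also in attribute `inconsistent`.
#' @export
check_printed_deltas <- function(records, printed, digits = 3) {
  kr <- paste(records$nucleus, records$molecule, records$site)
  kp <- paste(printed$nucleus, printed$molecule, printed$site)
  records$ddelta_printed <- printed$ddelta_printed[match(kr, kp)]
  tol <- 0.5 * 10^(-digits) + 1e-12
  records$consistent <- abs(records$delta_delta - records$ddelta_printed) <= tol
  structure(records, inconsistent = kr[!records$consistent %in% TRUE])
}

#' Rank sites by displacement magnitude
#'
#' Sorts the sites of one nucleus/molecule by \eqn{|\Delta\delta|}
#' descending, ties broken alphabetically by site label. An all-zero set is
#' flagged uninformative: ranking then carries no complexation signal.
#'
#' @param records A [compute_delta()] result.
#' @param nucleus,molecule Filters, e.g. `"1H"`, `"host"`.
#' @param k Optional: return only the top k sites.
#' @return A data.frame `site`, `delta_delta`, `abs_shift` sorted by
#'   `abs_shift`, with attribute `uninformative`.
#' @export
rank_shifts <- function(records, nucleus, molecule, k = NULL) {
  d <- records[records$nucleus == nucleus & records$molecule == molecule, , drop = FALSE]
  if (!nrow(d)) ck_stop("no records match the nucleus/molecule filter", "ck_no_matching_records")
  d$abs_shift <- abs(d$delta_delta)
  d <- d[order(-d$abs_shift, d$site), c("site", "delta_delta", "abs_shift")]
  if (!is.null(k)) d <- utils::head(d, k)
  rownames(d) <- NULL
  structure(d, uninformative = all(d$abs_shift == 0))
}

#' Default guest site-to-moiety map for anabasine
#'
#' Anabasine is a piperidine ring (sites 2-6; site 2 split into axial and
#' equatorial proton rows) bonded to a pyridine ring (sites 7-12).
#'
#' @return Named character vector mapping site label to moiety.
#' @export
anabasine_moiety_map <- function() {
  c("2" = "piperidine", "2-ax" = "piperidine", "2-eq" = "piperidine",
    "3" = "piperidine", "4" = "piperidine", "5" = "piperidine",
    "6" = "piperidine",
    "7" = "pyridine", "8" = "pyridine", "10" = "pyridine",
    "11" = "pyridine", "12" = "pyridine")
}

#' Aggregate NMR evidence for cavity inclusion
#'
#' For cyclodextrin hosts, the H-3 and H-5 protons line the inner cavity;
#' their appearance among the top-|Δδ| host proton shifts is the canonical
#' NMR signature of guest inclusion. On the guest side, the moiety (e.g.
#' piperidine vs pyridine ring) with the greatest mean proton |Δδ| indicates
#' which fragment enters the cavity.
#'
#' @param records A [compute_delta()] result containing host records
#'   (`molecule == "host"`); guest records optional.
#' @param cavity_sites Host sites lining the cavity. Default `c("3", "5")`.
#' @param k Number of top host sites inspected. Default 2.
#' @param moiety_map Named vector mapping guest site to moiety label; set to
#'   `NULL` to skip the guest-moiety call. Default [anabasine_moiety_map()].
#' @param nucleus Nucleus used for ranking. Default `"1H"`.
#' @return An object of class `inclusion_evidence`: `top_host_sites`,
#'   `cavity_sites`, `cavity_flag`, `top_guest_moiety` (or `NA`), and the
#'   per-moiety mean |Δδ| table.
#' @export
inclusion_evidence <- function(records, cavity_sites = c("3", "5"), k = 2,
                               moiety_map = anabasine_moiety_map(),
                               nucleus = "1H") {
  if (!length(cavity_sites)) ck_stop("cavity_sites must be non-empty", "ck_invalid_cavity_sites")
  top <- rank_shifts(records, nucleus, "host", k = k)
  cavity_flag <- length(intersect(as.character(top$site), as.character(cavity_sites))) > 0

  moiety_means <- NULL
  top_guest_moiety <- NA_character_
  has_guest <- any(records$molecule == "guest" & records$nucleus == nucleus)
  if (!is.null(moiety_map) && has_guest) {
    g <- records[records$molecule == "guest" & records$nucleus == nucleus, , drop = FALSE]
    g$moiety <- unname(moiety_map[as.character(g$site)])
    g <- g[!is.na(g$moiety), , drop = FALSE]
    if (nrow(g)) {
      means <- tapply(abs(g$delta_delta), g$moiety, mean)
      moiety_means <- data.frame(moiety = names(means), mean_abs_shift = as.numeric(means))
      moiety_means <- moiety_means[order(-moiety_means$mean_abs_shift, moiety_means$moiety), ]
      rownames(moiety_means) <- NULL
      top_guest_moiety <- moiety_means$moiety[1]
    }
  }
  structure(
    list(top_host_sites = as.character(top$site), top_host_shifts = top$delta_delta,
         cavity_sites = as.character(cavity_sites), cavity_flag = cavity_flag,
         top_guest_moiety = top_guest_moiety, moiety_means = moiety_means),
    class = "inclusion_evidence"
  )
}

#' @export
print.inclusion_evidence <- function(x, ...) {
  cat(sprintf("<inclusion_evidence> top host sites: %s | cavity {%s} hit: %s | guest moiety: %s\n",
              paste(x$top_host_sites, collapse = ", "),
              paste(x$cavity_sites, collapse = ","),
              x$cavity_flag, x$top_guest_moiety))
  invisible(x)
}
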