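#' Curated candidate-gene table from the seu ant gynoecium array screen
#'
#' The 31 synergy candidates recovered by the two-criterion screen of an
#' ATH1 microarray comparison of wild-type, seu-3, ant-1 and
#' seu-3 ant-1 double-mutant Arabidopsis gynoecia, transcribed with
#' their log2 genotype LSmeans, the -log10 p of the non-additivity
#' estimate, and annotation flags: GO transcriptional regulator
#' (`tf`), B3-superfamily membership (`b3`) and REM-subfamily
#' membership (`rem`).
#'
#' In this design the `ant` single mutant plays the role of genotype A
#' and `seu` of genotype B, so the additive expectation for the double
#' mutant is `lsmean_ant + lsmean_seu - lsmean_wt`.
#'
#' @return `data.frame` with 31 rows and columns `agi`, `title`, `tf`,
#'   `b3`, `rem`, `lsmean_wt`, `lsmean_ant`, `lsmean_seu`,
#'   `lsmean_double`, `neg_log10_p`.
#' @examples
#' tab <- candidate_table()
#' nrow(tab)        # 31
#' sum(tab$b3)      # 7
#' @export
candidate_table <- function() {
  tab <- data.frame(
    agi = c("At2g46870", "At3g17010", "At3g53310", "At5g18000", "At5g57720",
            "At3g19184", "At4g31610", "At4g24150", "At1g31310", "At1g51950",
            "At1g68640", "At2g34710", "At3g13960", "At3g55560", "At4g00180",
            "At4g37750", "At5g61850", "At1g02800", "At1g68780", "At2g27880",
            "At3g21560", "At1g01110", "At1g03710", "At1g03720", "At1g70560",
            "At1g73590", "At2g21050", "At4g25240", "At5g07280", "At5g17080",
            "At5g48900"),
    title = c("NGATHA1 - B3 domain", "REM22 - B3 domain",
              "REM16 - B3 domain", "REM20, VERDANDI - B3 domain",
              "REM15 - B3 domain", "REM1 - B3 domain", "REM34 - B3 domain",
              "AtGRF8, transcriptional regulator", "myb-like domain",
              "IAA18, transcription factor", "PERIANTHIA, DNA binding",
              "PHABULOSA, transcription factor",
              "AtGRF5, transcriptional regulator", "AGF2, DNA-binding protein",
              "YABBY3, transcription factor", "AINTEGUMENTA, DNA binding",
              "LEAFY, transcription factor", "ATCEL2, cellulase hydrolase",
              "leucine-rich repeat family protein", "AGO5, argonaute protein",
              "UGT84A2, UDP-glycosyltransferase", "IQD18, calmodulin binding",
              "cystatin-related", "cathepsin-related", "TAA1 - auxin synthesis",
              "PIN1, auxin transporter", "LAX2 - auxin influx carrier",
              "SKS1 (SKU5 SIMILAR 1)", "EXCESS MICROSPOROCYTES1 kinase",
              "cathepsin-related", "pectate lyase family protein"),
    tf = c(rep(TRUE, 17), rep(FALSE, 14)),
    b3 = c(rep(TRUE, 7), rep(FALSE, 24)),
    rem = c(FALSE, rep(TRUE, 6), rep(FALSE, 24)),
    lsmean_wt = c(8.42, 10.03, 11.09, 8.55, 9.45, 8.59, 10.18, 9.56, 9.64,
                  9.56, 9.82, 9.49, 9.21, 8.47, 9.27, 10.80, 9.76, 11.93,
                  8.41, 10.19, 9.73, 8.85, 10.19, 9.00, 9.61, 10.42, 9.95,
                  9.77, 10.47, 9.42, 8.68),
    lsmean_ant = c(8.52, 9.80, 11.00, 7.72, 9.48, 7.77, 10.12, 9.03, 9.71,
                   9.18, 9.04, 9.21, 9.30, 8.00, 8.38, 9.65, 8.96, 11.47,
                   8.26, 9.65, 9.71, 8.78, 10.16, 8.16, 9.07, 9.99, 9.57,
                   10.09, 10.54, 8.56, 8.39),
    lsmean_seu = c(7.85, 8.60, 10.50, 8.54, 8.97, 8.37, 9.53, 9.35, 9.22,
                   9.37, 9.31, 8.95, 8.25, 8.22, 8.64, 10.69, 8.90, 11.18,
                   7.74, 9.98, 8.87, 8.30, 9.78, 8.41, 9.07, 10.04, 10.23,
                   9.16, 10.03, 9.53, 8.22),
    lsmean_double = c(7.17, 7.37, 9.93, 7.02, 8.45, 7.08, 8.98, 8.24, 8.86,
                      8.33, 8.09, 8.24, 7.84, 7.26, 7.05, 8.91, 7.41, 9.95,
                      6.87, 8.94, 8.37, 7.63, 8.81, 7.05, 7.62, 8.70, 8.76,
                      8.75, 9.42, 6.81, 7.50),
    neg_log10_p = c(5.06, 2.98, 1.58, 3.51, 2.01, 1.65, 1.12, 1.78, 1.84,
                    4.17, 1.22, 2.90, 1.61, 2.18, 2.50, 2.18, 1.58, 1.90,
                    5.94, 2.01, 1.38, 4.87, 4.06, 2.34, 4.90, 4.02, 6.11,
                    3.63, 4.56, 6.34, 2.01),
    stringsAsFactors = FALSE)
  tab
}

#' Synergy consistency of the curated candidate table
#'
#' Recomputes, for every row of the candidate table, the non-additivity
#' deviation `delta = lsmean_double - (lsmean_ant + lsmean_seu -
#' lsmean_wt)` and counts the rows with `delta < 0` (strictly), i.e.
#' the rows whose double-mutant LSmean falls below the additive
#' expectation. All 31 curated candidates satisfy this by construction
#' of the screen that produced them.
#'
#' @param tab a candidate table as returned by [candidate_table()].
#' @return integer count of rows with `delta < 0`, with the per-row
#'   deviations attached as attribute `"delta"` (named by AGI).
#' @examples
#' candidate_table_consistency()
#' @export
candidate_table_consistency <- function(tab = candidate_table()) {
  need <- c("agi", "lsmean_wt", "lsmean_ant", "lsmean_seu", "lsmean_double")
  if (!all(need %in% names(tab))) stop("candidate table needs columns ",
                                       paste(need, collapse = ", "))
  delta <- tab$lsmean_double -
    additive_expectation(tab$lsmean_wt, tab$lsmean_ant, tab$lsmean_seu)
  names(delta) <- tab$agi
  structure(sum(delta < 0), delta = delta)
}

#' Curated qRT-PCR verification tables
#'
#' Mean normalized expression (relative to the APT1 reference,
#' At1g27450), standard error of the mean over four biological
#' replicates, and Tukey HSD letters for the qRT-PCR verification of
#' candidates under-expressed (`direction = "under"`) or over-expressed
#' (`"over"`) in the seu ant double mutant. One under-expressed
#' candidate was not detected by qPCR and carries `NA` values.
#'
#' @param direction `"under"` or `"over"`.
#' @return long-format `data.frame` with columns `gene_id`,
#'   `gene_name`, `genotype` (one of `"wt"`, `"seu"`, `"ant"`,
#'   `"seu ant"`), `mean`, `sem`, `letters`.
#' @examples
#' qv <- qpcr_verification_table("under")
#' subset(qv, gene_name == "REM16")
#' @export
qpcr_verification_table <- function(direction = c("under", "over")) {
  direction <- match.arg(direction)
  geno <- c("wt", "seu", "ant", "seu ant")
  build <- function(gene_id, gene_name, ...) {
    v <- list(...)   # four (mean, sem, letters) triples in genotype order
    data.frame(gene_id = gene_id, gene_name = gene_name, genotype = geno,
               mean = vapply(v, function(z) as.numeric(z[[1]]), numeric(1)),
               sem = vapply(v, function(z) as.numeric(z[[2]]), numeric(1)),
               letters = vapply(v, function(z) as.character(z[[3]]),
                                character(1)),
               stringsAsFactors = FALSE)
  }
  rows <- if (direction == "under") list(
    build("At4g31610", "REM34", list(0.43, 0.03, "A"), list(0.25, 0.04, "B"),
          list(0.33, 0.01, "AB"), list(0.12, 0.02, "C")),
    build("At2g46870", "NGA1", list(0.11, 0.01, "A"), list(0.04, 0.003, "C"),
          list(0.09, 0.004, "B"), list(0.01, 0.001, "D")),
    build("At1g68640", "PAN", list(0.16, 0.02, "A"), list(0.08, 0.003, "B"),
          list(0.06, 0.005, "BC"), list(0.02, 0.005, "C")),
    build("At1g31310", "myb-domain", list(NA, NA, NA), list(NA, NA, NA),
          list(NA, NA, NA), list(NA, NA, NA)),
    build("At3g61970", "NGA2", list(0.03, 0.002, "A"), list(0.01, 0.003, "C"),
          list(0.02, 0.002, "B"), list(0.001, 0.0002, "C")),
    build("At3g55560", "AGF2", list(0.07, 0.01, "A"), list(0.05, 0.005, "B"),
          list(0.03, 0.004, "BC"), list(0.01, 0.002, "C")),
    build("At3g53310", "REM16", list(15.78, 0.91, "A"), list(7.35, 0.41, "C"),
          list(12.25, 0.60, "B"), list(4.15, 0.67, "D")),
    build("At3g21560", "UGT84A2", list(0.55, 0.03, "A"), list(0.22, 0.04, "B"),
          list(0.41, 0.04, "A"), list(0.11, 0.02, "B")),
    build("At5g18000", "VDD", list(0.12, 0.01, "A"), list(0.12, 0.02, "A"),
          list(0.04, 0.01, "B"), list(0.01, 0.001, "B")),
    build("At1g68780", "LRR type", list(0.11, 0.01, "A"), list(0.04, 0.00, "C"),
          list(0.07, 0.01, "B"), list(0.01, 0.001, "D"))
  ) else list(
    build("At1g20450", "ERD10", list(0.03, 0.01, "C"), list(0.09, 0.03, "B"),
          list(0.03, 0.002, "C"), list(0.16, 0.02, "A")),
    build("At2g15970", "COR413", list(0.05, 0.01, "C"), list(0.16, 0.02, "B"),
          list(0.03, 0.01, "C"), list(0.30, 0.04, "A")),
    build("At1g26960", "ATHB23", list(0.03, 0.004, "C"), list(0.06, 0.004, "B"),
          list(0.03, 0.001, "C"), list(0.11, 0.01, "A")),
    build("At2g33380", "RD20", list(0.04, 0.01, "BC"), list(0.08, 0.005, "B"),
          list(0.02, 0.003, "C"), list(0.15, 0.03, "A")),
    build("At1g05850", "POM1", list(0.40, 0.04, "B"), list(0.42, 0.01, "B"),
          list(0.35, 0.03, "B"), list(0.66, 0.07, "A")),
    build("At1g69780", "ATHB13", list(0.23, 0.04, "BC"), list(0.19, 0.02, "C"),
          list(0.29, 0.02, "B"), list(0.45, 0.02, "A")),
    build("At3g11090", "LBD21", list(0.03, 0.004, "B"), list(0.04, 0.003, "B"),
          list(0.02, 0.003, "B"), list(0.08, 0.01, "A")),
    build("At4g18960", "AG", list(19.23, 2.36, "A"), list(20.21, 2.01, "A"),
          list(15.82, 1.06, "A"), list(22.94, 3.23, "A"))
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
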