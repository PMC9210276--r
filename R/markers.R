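#' Packaged domain-marker peptides
#'
#' Fixed 30-aa synthetic signature peptides standing for the conserved domains
#' of DIRS-order retrotransposons: gag, reverse transcriptase (RT), RNase H
#' (RH), DAM-methyltransferase (MT, DIRS-like only), tyrosine recombinase (YR)
#' and the SGNH hydrolase (Ngaro-like only). They are invented sequences (not
#' database motifs) that the synthetic generator writes into ORFs and
#' [scan_domains()] recovers, so domain scanning needs no external database.
#'
#' @return Named character vector of six 30-aa peptides.
#' @export
domain_markers <- function() {
  c(
    GAG  = "WQENPHRCKLTVYDAMIGSFWQHKNPELRC",
    RT   = "DFLKPHGQYWMRTECNAVSLIDHKWPFQYR",
    RH   = "NVTYEQWHACKRPLMGDSFIECHVNQWYTR",
    MT   = "GKWDNPYFSQHLRTVAMECIGKWPNDYHSQ",
    YR   = "HRYLDWQKNPFMSIGAVTCEHRWLDYQNPK",
    SGNH = "SPGNHDWYKQECVFTRLMAISGPNHDWYKR"
  )
}

#' Expected domain order per superfamily
#'
#' The diagnostic coding-domain order of complete elements: DIRS-like elements
#' carry gag, then RT/RH (optionally MT), then YR; Ngaro-like elements carry
#' gag, RT/RH, YR and finally an SGNH hydrolase.
#'
#' @param superfamily `"DIRS-like"` or `"Ngaro-like"`.
#' @param with_mt For DIRS-like, whether the MT domain is expected.
#' @return Character vector of marker labels in 5' to 3' order.
#' @export
expected_domain_order <- function(superfamily = c("DIRS-like", "Ngaro-like"),
                                  with_mt = TRUE) {
  superfamily <- match.arg(superfamily)
  if (superfamily == "DIRS-like") {
    if (with_mt) c("GAG", "RT", "RH", "MT", "YR") else c("GAG", "RT", "RH", "YR")
  } else {
    c("GAG", "RT", "RH", "YR", "SGNH")
  }
}
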