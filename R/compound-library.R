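#' Default compound library with drug-class annotation
#'
#' A 115-entry compound/combination panel mirroring the composition of a
#' pediatric-AML screening library: first-line chemotherapy, a BCL2
#' inhibitor (venetoclax) and its combinations, HDAC inhibitors,
#' proteasome inhibitors, FLT3 inhibitors, a broad kinase-inhibitor arm
#' and a mixed "other" arm. Every screened compound maps to exactly one
#' class; singleton classes are permitted.
#'
#' @return A data.frame with columns `compound` and `class`.
#' @export
default_compound_library <- function() {
  lib <- list(
    "BCL2 inhibitor" = "venetoclax",
    "venetoclax combination" = paste0("venetoclax_", c(
      "azacitidine", "cytarabine", "idasanutlin", "quizartinib",
      "gilteritinib", "panobinostat", "bortezomib", "daunorubicin",
      "midostaurin"
    )),
    "HDAC inhibitor" = c(
      "panobinostat", "vorinostat", "entinostat", "romidepsin", "quisinostat"
    ),
    "proteasome inhibitor" = c("bortezomib", "carfilzomib", "ixazomib"),
    "FLT3 inhibitor" = c("quizartinib", "gilteritinib"),
    "chemotherapy" = c(
      "cytarabine", "daunorubicin", "doxorubicin", "idarubicin",
      "mitoxantrone", "etoposide", "fludarabine", "clofarabine",
      "mercaptopurine", "fluorouracil", "methotrexate", "aminopterin",
      "thiotepa", "irinotecan", "topotecan", "vincristine", "mafosfamide",
      "busulfan", "gemcitabine", "decitabine"
    ),
    "kinase inhibitor" = c(
      "dasatinib", "nilotinib", "imatinib", "ponatinib", "ruxolitinib",
      "tofacitinib", "ibrutinib", "idelalisib", "copanlisib", "alpelisib",
      "everolimus", "temsirolimus", "trametinib", "selumetinib",
      "cobimetinib", "palbociclib", "ribociclib", "abemaciclib",
      "erlotinib", "gefitinib", "ceritinib", "crizotinib", "lapatinib",
      "pazopanib", "sunitinib"
    ),
    "other" = c(
      "idasanutlin", "navitoclax", "pinometostat", "azacitidine",
      "tazemetostat", "birabresib", "pracinostat_free", "volasertib",
      "alisertib", "barasertib", "tozasertib", "danusertib",
      sprintf("cmpd%02d", seq_len(38))
    )
  )
  out <- data.frame(
    compound = unlist(lib, use.names = FALSE),
    class = rep(names(lib), lengths(lib)),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(out$compound), nrow(out) == 115L)
  out
}
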