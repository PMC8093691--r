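#' Published 21-tag movement sequence fixture
#'
#' The simplified movement sequences of the 21 radio-tagged chimney swifts
#' tracked among 10 southern Nova Scotia roost sites in the 2019 Motus
#' season, keyed by tag id. All birds were tagged at Caledonia. Sequences
#' are stored collapsed: birds recorded only at the tagging site (whether
#' they stayed or left and returned without being detected elsewhere)
#' appear as the single entry `"Caledonia"`, which contributes no network
#' link either way.
#'
#' @return Named list of 21 collapsed movement sequences, byte-stable
#'   across calls.
#' @export
#' @examples
#' seqs <- table1_fixture()
#' length(seqs)            # 21 tags
#' seqs[["628"]]           # the longest sequence, 7 roost visits
table1_fixture <- function() {
  list(
    "247" = c("Caledonia", "Bridgetown"),
    "250" = c("Caledonia", "Middleton", "Bridgetown"),
    "255" = c("Caledonia"),
    "256" = c("Caledonia", "Bridgetown", "Middleton", "Bridgetown"),
    "257" = c("Caledonia"),
    "258" = c("Caledonia", "Wolfville", "Bridgetown", "Caledonia", "Bridgetown"),
    "260" = c("Caledonia"),
    "264" = c("Caledonia", "Bridgetown", "Caledonia"),
    "265" = c("Caledonia", "Middleton", "Bridgetown"),
    "624" = c("Caledonia", "Marshalltown", "Upper Clements", "Caledonia"),
    "626" = c("Caledonia"),
    "628" = c("Caledonia", "Upper Clements", "Caledonia", "Blandford",
              "Upper Clements", "Caledonia", "Weymouth"),
    "629" = c("Caledonia"),
    "631" = c("Caledonia", "Upper Clements"),
    "637" = c("Caledonia", "Upper Clements"),
    "640" = c("Caledonia", "Liverpool", "Upper Clements"),
    "641" = c("Caledonia", "Marshalltown", "Weymouth"),
    "643" = c("Caledonia", "Upper Clements", "Caledonia", "Wolfville",
              "Marshalltown"),
    "644" = c("Caledonia", "Upper Clements", "Marshalltown", "Upper Clements"),
    "645" = c("Caledonia", "Jordan Bay", "Weymouth"),
    "650" = c("Caledonia", "Weymouth", "Caledonia")
  )
}
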