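#' EquiFACS code vocabulary
#'
#' The set of EquiFACS codes the package validates against: action units
#' (`AU*`), horse-specific supplementary action units (`AUH*`), action
#' descriptors (`AD*`), ear action descriptors (`EAD*`) and the visibility
#' code `VC74` marking unscorable footage. Head-movement descriptors
#' (AD51--AD55) are excluded, matching annotation templates that omit them.
#'
#' @param include_fmi logical; if `TRUE` the composite facial-movement-index
#'   code [fmi_code()] ("ear flicker") is part of the vocabulary, so event
#'   tables that have already been through [apply_ear_flicker()] validate.
#' @return character vector of valid codes.
#' @seealso [read_events()], [apply_ear_flicker()]
#' @export
#' @examples
#' "EAD104" %in% equifacs_vocabulary()
equifacs_vocabulary <- function(include_fmi = TRUE) {
  codes <- c(
    # upper face
    "AU101", "AU143", "AU145", "AU47", "AU5", "AD1",
    # lower face
    "AU10", "AU113", "AU12", "AU16", "AU17", "AU122", "AU25", "AU26", "AU27",
    "AUH13", "AUH21", "AD19", "AD29", "AD30", "AD81", "AD133", "AD160",
    # nostril
    "AD38",
    # ears
    "EAD101", "EAD102", "EAD103", "EAD104",
    # visibility
    "VC74"
  )
  if (include_fmi) codes <- c(codes, fmi_code())
  codes
}

#' Code used for the "ear flicker" facial movement index
#'
#' @return the character constant `"FMI_EAR_FLICKER"`.
#' @export
fmi_code <- function() "FMI_EAR_FLICKER"

#' @keywords internal
vc_code <- function() "VC74"

ear_codes <- function() c("EAD101", "EAD104")

#' Condition and group labels
#'
#' Study designs supported by the package use two horse groups --
#' privately-owned (`PRI`) and university-owned (`UNI`) -- and three
#' conditions: `baseline` plus the two interventions `transportation`
#' and `isolation`.
#'
#' @return character vector of labels.
#' @export
study_conditions <- function() c("baseline", "transportation", "isolation")

#' @rdname study_conditions
#' @export
study_groups <- function() c("PRI", "UNI")
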