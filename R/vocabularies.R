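#' Gesture label vocabularies
#'
#' Two registered vocabularies are supported: `"FM-10"`, the ten finger
#' movements (hand close `H-C`; thumb paired with little/ring/middle/index
#' `T-L`, `T-R`, `T-M`, `T-I`; and the single-finger bends `T`, `L`, `R`,
#' `M`, `I`), and `"HG-6"`, the six hand grasps (lateral `LG`, tip `TG`,
#' cylindrical `CG`, hook `HG`, spherical `SG`, palmar `PG`).
#'
#' @param name Vocabulary name, `"FM-10"` or `"HG-6"`.
#' @return Character vector of gesture labels, in canonical order.
#' @examples
#' gesture_vocabulary("HG-6")
#' @export
gesture_vocabulary <- function(name = c("FM-10", "HG-6")) {
  name <- match.arg(name)
  switch(name,
    "FM-10" = c("H-C", "T-L", "T-R", "T-M", "T-I", "T", "L", "R", "M", "I"),
    "HG-6"  = c("LG", "TG", "CG", "HG", "SG", "PG")
  )
}

# resolve a vocabulary argument: a registered name or an explicit label vector
resolve_vocabulary <- function(vocabulary) {
  if (is.character(vocabulary) && length(vocabulary) == 1 &&
      vocabulary %in% c("FM-10", "HG-6")) {
    return(gesture_vocabulary(vocabulary))
  }
  vocabulary <- as.character(vocabulary)
  if (anyDuplicated(vocabulary)) stop("vocabulary labels must be unique")
  if (length(vocabulary) < 1) stop("vocabulary must contain at least one label")
  vocabulary
}
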