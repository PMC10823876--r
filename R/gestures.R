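#' Gesture label table
#'
#' The five indicative gestures recognized by the pipeline, with their
#' integer class labels. Label ids are the class codes used throughout:
#' 1 = thumbs up, 2 = "V" sign, 3 = "OK" sign, 4 = clenched fist,
#' 5 = open hand.
#'
#' @return A data.frame with columns `id` (integer 1..5) and `name`
#'   (character).
#' @examples
#' gesture_labels()
#' @export
gesture_labels <- function() {
  data.frame(
    id = 1:5,
    name = c("thumbs_up", "v_sign", "ok_sign", "fist", "open_hand"),
    stringsAsFactors = FALSE
  )
}

#' Resolve a gesture given as id or name to its integer id
#'
#' @param gesture integer id in 1..5 or one of the gesture names.
#' @return integer gesture id.
#' @keywords internal
gesture_id <- function(gesture) {
  g <- gesture_labels()
  if (is.numeric(gesture)) {
    id <- as.integer(gesture)
    if (length(id) != 1L || is.na(id) || !(id %in% g$id)) {
      stop("unknown gesture id: ", gesture, " (valid ids are 1..5)")
    }
    return(id)
  }
  if (is.character(gesture)) {
    hit <- match(gesture, g$name)
    if (length(gesture) != 1L || is.na(hit)) {
      stop("unknown gesture name: '", gesture, "' (valid names: ",
           paste(g$name, collapse = ", "), ")")
    }
    return(g$id[hit])
  }
  stop("gesture must be an integer id or a gesture name")
}
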