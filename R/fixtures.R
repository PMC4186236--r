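#' Generate a randomized arena fixture
#'
#' Deterministic per \code{(kind, seed)}. Four kinds cover the behavioural
#' protocols:
#' \describe{
#'   \item{open_field}{12 x 12 open arena, one appetitive field with a
#'     single Gaussian source and a food site at its peak. Used for the
#'     homeostatic and allostatic properties.}
#'   \item{lever_box}{10 x 10 conditioning chamber: a lever/food site at a
#'     randomized interior position, marked by a lever landmark, with a food
#'     odour field centred on it and a context cue covering the box.}
#'   \item{corridor_maze}{18 x 6 corridor with a goal site at the east end
#'     and pocket alcoves holding distracter landmarks (features within the
#'     evidence bandwidth of the goal landmark's) and distracter odour
#'     sources — local maxima of the goal field that trap purely reactive
#'     control.}
#'   \item{foraging}{20 x 20 arena with a home position, two food sites with
#'     short-range odour basins, and a ring of distinct landmarks that makes
#'     percepts position-specific everywhere (for allocentric recall).}
#' }
#'
#' @param kind one of \code{"open_field"}, \code{"lever_box"},
#'   \code{"corridor_maze"}, \code{"foraging"}.
#' @param seed integer seed.
#' @param n_distracters number of distracter pockets (corridor_maze only).
#' @return a list with the arena and protocol anchors (start pose, etc.).
#' @export
generate_arena_fixture <- function(kind, seed, n_distracters = 2L) {
  reg <- rng_registry(seed)
  s <- rng_stream(reg, "fixtures")
  feat <- function(n) {
    # distinct unit-norm feature vectors
    M <- matrix(stream_runif(s, 3L * n, -1, 1), ncol = 3)
    M / sqrt(rowSums(M^2))
  }
  switch(kind,
    open_field = {
      cpos <- c(stream_runif(s, 1, 3, 9), stream_runif(s, 1, 3, 9))
      a <- arena(12, 12,
        landmarks = list(list(id = "beacon", pos = cpos, features = c(1, 0, 0))),
        outcome_sites = list(list(id = "food_site", pos = cpos,
                                  outcome_id = "food", radius = 0.8)),
        fields = list(food = affordance_field("food",
          list(list(center = cpos, amplitude = 1, sigma = 3)))))
      list(kind = kind, seed = seed, arena = a,
           start = agent_pose(1, 1, 0), goal_pos = cpos)
    },
    lever_box = {
      lpos <- c(stream_runif(s, 1, 2.5, 7.5), stream_runif(s, 1, 2.5, 7.5))
      corners <- rbind(c(1.5, 1.5), c(8.5, 1.5), c(1.5, 8.5), c(8.5, 8.5))
      dc <- sqrt((corners[, 1] - lpos[1])^2 + (corners[, 2] - lpos[2])^2)
      start_xy <- corners[which.max(dc), ]
      a <- arena(10, 10,
        landmarks = list(list(id = "lever", pos = lpos,
                              features = feat(1)[1, ])),
        cues = list(list(id = "context_train", pos = c(5, 5), radius = 20,
                         channel = 1L)),
        outcome_sites = list(list(id = "lever_site", pos = lpos,
                                  outcome_id = "food", radius = 0.8)),
        fields = list(food_odor = affordance_field("food_odor",
          list(list(center = lpos, amplitude = 1, sigma = 2)))))
      list(kind = kind, seed = seed, arena = a,
           start = agent_pose(start_xy[1], start_xy[2], 0), goal_pos = lpos)
    },
    corridor_maze = {
      goal <- c(16.5, 3)
      gfeat <- feat(1)[1, ]
      lms <- list(list(id = "goal_beacon", pos = goal, features = gfeat))
      # wall cues give the percept lateral and longitudinal structure, so
      # evidence matching can localize along the corridor
      WF <- feat(6)
      wall_xy <- rbind(c(3, 0.2), c(7, 0.2), c(11, 0.2), c(15, 0.2),
                       c(2, 5.8), c(14, 5.8))
      for (wi in 1:6) {
        lms <- c(lms, list(list(id = paste0("wall_", wi),
                                pos = wall_xy[wi, ], features = WF[wi, ])))
      }
      walls <- list()
      sources <- list(list(center = goal, amplitude = 1, sigma = 2.5))
      if (n_distracters > 0L) {
        px <- seq(5, 11, length.out = n_distracters)
        for (i in seq_len(n_distracters)) {
          x <- px[i]
          dpos <- c(x, 5.2)
          # pocket: two side walls and a lipped opening facing the corridor
          walls <- c(walls, list(
            c(x - 1.2, 4.2, x - 1.2, 6), c(x + 1.2, 4.2, x + 1.2, 6),
            c(x - 1.2, 4.2, x - 0.4, 4.2), c(x + 0.4, 4.2, x + 1.2, 4.2)))
          # distracter features resemble the goal's (within sigma_e)
          df <- gfeat + stream_runif(s, 3, -0.2, 0.2)
          lms <- c(lms, list(list(id = paste0("distracter_", i), pos = dpos,
                                  features = df)))
          sources <- c(sources, list(list(center = dpos, amplitude = 0.6,
                                          sigma = 0.8)))
        }
      }
      a <- arena(18, 6, walls = walls, landmarks = lms,
        cues = list(list(id = "goal_cue", pos = goal, radius = 2,
                         channel = 1L)),
        outcome_sites = list(list(id = "goal_site", pos = goal,
                                  outcome_id = "food", radius = 0.8)),
        fields = list(food_odor = affordance_field("food_odor", sources)))
      list(kind = kind, seed = seed, arena = a,
           start = agent_pose(1, 3, 0), goal_pos = goal)
    },
    foraging = {
      home <- c(10, 2)
      food1 <- c(5 + stream_runif(s, 1, -1, 1), 14 + stream_runif(s, 1, -1, 1))
      food2 <- c(15 + stream_runif(s, 1, -1, 1), 14 + stream_runif(s, 1, -1, 1))
      ring_t <- 2 * pi * (0:7) / 8
      F <- feat(10)
      lms <- lapply(1:8, function(i) {
        list(id = paste0("ring_", i),
             pos = c(10 + 8 * cos(ring_t[i]), 10 + 7.5 * sin(ring_t[i])),
             features = F[i, ])
      })
      lms <- c(lms,
               list(list(id = "food_lm_1", pos = food1, features = F[9, ]),
                    list(id = "food_lm_2", pos = food2, features = F[10, ])))
      a <- arena(20, 20, landmarks = lms,
        outcome_sites = list(
          list(id = "food_site_1", pos = food1, outcome_id = "food",
               radius = 0.8),
          list(id = "food_site_2", pos = food2, outcome_id = "food",
               radius = 0.8)),
        fields = list(food_odor = affordance_field("food_odor", list(
          list(center = food1, amplitude = 1, sigma = 1.2),
          list(center = food2, amplitude = 1, sigma = 1.2)))))
      list(kind = kind, seed = seed, arena = a,
           start = agent_pose(home[1], home[2], pi / 2), home = home)
    },
    stop("generate_arena_fixture: unknown kind '", kind, "'")
  )
}

#' Serialize an arena to its JSON specification
#'
#' Keys: \code{size}, \code{walls}, \code{landmarks}, \code{cues},
#' \code{outcome_sites}, \code{fields}; coordinates in arena units, origin
#' at the bottom-left.
#'
#' @param a a [arena()].
#' @param path optional file path; when given, JSON is written there.
#' @return the JSON string, invisibly when written to file.
#' @export
write_arena <- function(a, path = NULL) {
  spec <- list(
    size = c(a$width, a$height),
    walls = a$walls,
    landmarks = a$landmarks,
    cues = a$cues,
    outcome_sites = a$outcome_sites,
    fields = lapply(a$fields, function(f) {
      list(field_id = f$field_id, sources = f$sources)
    })
  )
  js <- jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read an arena from its JSON specification
#' @param path JSON file path.
#' @return a validated [arena()].
#' @export
read_arena <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tolist <- function(x) lapply(x, function(e) {
    e$pos <- as.numeric(unlist(e$pos))
    if (!is.null(e$features)) e$features <- as.numeric(unlist(e$features))
    e
  })
  arena(spec$size[[1]], spec$size[[2]],
        walls = lapply(spec$walls, function(w) as.numeric(unlist(w))),
        landmarks = tolist(spec$landmarks),
        cues = tolist(spec$cues),
        outcome_sites = tolist(spec$outcome_sites),
        fields = lapply(spec$fields, function(f) {
          affordance_field(f$field_id, lapply(f$sources, function(src) {
            list(center = as.numeric(unlist(src$center)),
                 amplitude = src$amplitude, sigma = src$sigma)
          }))
        }))
}
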