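# Straight-line re-implementation of the four printed weight-update equations
# for a single unit, used as an independent oracle against apply_update().
# State is a flat named vector c(S_OA, S_OB, S_SX, S_SY); stimuli are
# (object, scene) with indicator semantics; responses are linear-subtractive.
oracle_step <- function(w, fsi, object, scene, reward, ls = 0.01) {
  I_OA <- as.numeric(identical(object, "A"))
  I_OB <- as.numeric(identical(object, "B"))
  I_SX <- as.numeric(identical(scene, "X"))
  I_SY <- as.numeric(identical(scene, "Y"))
  msn <- I_OA * w[["S_OA"]] + I_OB * w[["S_OB"]] +
    I_SX * w[["S_SX"]] + I_SY * w[["S_SY"]] -
    (I_SX * fsi[["X"]] + I_SY * fsi[["Y"]])
  w[["S_OA"]] <- w[["S_OA"]] + I_OA * msn * reward * ls
  w[["S_OB"]] <- w[["S_OB"]] + I_OB * msn * reward * ls
  w[["S_SX"]] <- w[["S_SX"]] + I_SX * msn * reward * ls
  w[["S_SY"]] <- w[["S_SY"]] + I_SY * msn * reward * ls
  attr(w, "msn") <- msn
  w
}

oracle_init <- function() c(S_OA = 1, S_OB = 1, S_SX = 1, S_SY = 1)

# A fixed 10-trial stimulus/reward sequence covering all four (object, scene)
# combinations with both reward signals.
oracle_sequence <- function() {
  data.frame(
    object = c("A", "B", "A", "B", "A", "B", "A", "B", "A", "B"),
    scene  = c("X", "X", "Y", "Y", "X", "Y", "Y", "X", "X", "Y"),
    reward = c(1, -0.5, -0.5, 1, 1, 1, -0.5, -0.5, 1, 1),
    stringsAsFactors = FALSE
  )
}
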