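# BoneFrame

Body-coordinate morphometry, virtual reconstruction, and sesamoid-groove
analysis of foot bone surface meshes.

## The problem

Fossil skeletal elements are usually damaged, which blocks quantitative
comparison of joint morphology between fossil hominins and modern
humans. A case in point is the first metatarsophalangeal joint (MTPJ) —
the "big toe joint", which transmits more than half of forefoot load
during gait. Its first metatarsal head (FMH) carries two plantar
grooves in which the sesamoid bones glide; the curvature of those
grooves, and whether the two grooves share a common axis, reflect how
the joint was loaded.

BoneFrame implements a fully inertial (landmark-free) pipeline for this
kind of analysis on closed triangular surface meshes (STL/PLY/OBJ,
millimetres), as used for *Homo naledi*'s first MTPJ and ten modern
athletes:

1. **Body coordinate system.** For each bone, the centre of mass and
   inertia tensor of the enclosed uniform solid are computed exactly
   from the surface (divergence theorem). The eigenvectors of the
   inertia tensor — the principal axes of inertia, ordered by ascending
   principal moment so axis 1 is the elongation axis — define the
   bone's intrinsic *body frame*.
2. **Standardization.** A subject's metatarsal, proximal and distal
   phalanx are scaled by one uniform factor `s = 100 / metatarsal
   length`, so every subject's metatarsal has body-frame length 100 and
   all shape ratios are preserved.
3. **Donor selection.** Each bone's length, width, height, surface area
   and volume are tabulated and divided by the reference (fossil)
   subject's values. The donor is the subject minimizing the mean of
   its 15 ratios.
4. **Reconstruction.** The damaged bone and the donor are overlapped in
   their shared body frames (the 180° sign ambiguity of principal axes
   is resolved automatically, and the pose is polished by a trimmed
   rigid registration). The donor-surface region farther than a
   threshold from the damaged surface marks the defect; the damaged
   solid is united, in the voxel domain, with the donor solid
   restricted to the defect, re-surfaced watertight, and restored to
   its original scale.
5. **Groove quantification.** Cross-sections rotating in 0.5° steps
   about the head's vertical axis are cut through each groove; the
   concave groove arc is extracted from the contour and an algebraic
   least-squares circle is fitted. The *curvature diameter* (CD) of a
   groove is twice the radius at the rotation angle minimizing the
   fitted diameter (an oblique slice of a cylindrical groove always
   fits a larger circle). The grooves are *parallel* when medial and
   lateral minima occur in the same section (angle difference within
   tolerance, default one 0.5° step) — i.e. the joint flexes about a
   single axis.

A parametric generator of bone-like solids (superellipsoid shaft,
spherical head, two carved cylindrical grooves of known radius and
skew, plus plane-clip / sphere-bite damage operators) provides ground
truth for every stage.

## Worked example

Donor ranking on the packaged measurement table (ten athletes and the
*H. naledi* fossil, all metatarsal lengths standardized to 100):

```r
library(BoneFrame)
tab <- mtpjMeasurements()
rt  <- ratioTable(tab, reference = "H. naledi")
sapply(setdiff(unique(tab$subject), "H. naledi"),
       function(s) donorScore(rt, s))
#> Basketball player 1 Basketball player 2 Basketball player 3 Basketball player 4
#>              1.0479              1.0560              1.1913              1.1816
#>  Badminton player 1  Badminton player 2              Jumper            Wrestler
#>              1.2343              1.2139              1.0471              1.1987
#>          Volleyball              Runner
#>              1.0163              1.0127
selectDonor(rt)
#> [1] "Runner"
```

The middle-distance runner has the smallest mean ratio (1.0127): its
MTPJ is dimensionally closest to the fossil's, so it serves as the
reconstruction donor.

Groove analysis of a synthetic metatarsal with 4 mm grooves skewed 2°:

```r
b <- makeBone(boneParams(grooveSkewMedial = 2, grooveSkewLateral = 2,
                         meshResolution = 3))
massProperties(b$mesh)
#> MassProperties: V = 13439.753 mm^3, A = 3870.408 mm^2
#>   COM = (-18.891, -0.039, 0.227) mm
#>   principal moments = 4.272e+05, 5.744e+06, 5.828e+06 mm^5
fits <- lapply(c("medial", "lateral"), function(sd)
  scanGrooveCD(b$mesh, side = sd, angleRange = 6))
fits[[1]]
#> GrooveFit [medial]: CD = 7.989 mm at rotation +1.61 deg (rms 0.0008 mm, 48 pts)
fits[[2]]
#> GrooveFit [lateral]: CD = 7.999 mm at rotation +1.98 deg (rms 0.0012 mm, 47 pts)
parallelismTest(fits[[1]], fits[[2]])
#> ParallelismResult: parallel (|angle difference| = 0.36 deg, tolerance 0.50 deg)
```

Both carved radii (true CD 8 mm) are recovered within 0.15%, the 2°
skew within 0.4°, and the equal-skew pair is correctly judged parallel.

A command-line surface over the same functions is installed at
`inst/scripts/boneframe.R` (subcommands `simulate`, `measure`,
`compare`, `align`, `reconstruct`, `groove`, `pipeline`; exit codes 0
ok / 1 computational failure / 2 input error).

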