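# Calibration curve files

The published radiocarbon calibration curves are not distributed with this
package. To run the diet-corrected calibration against the real curves,
download the two public `.14c` tables

- `intcal20.14c` (Northern Hemisphere atmospheric curve)
- `marine20.14c` (global marine curve)

from the IntCal working-group distribution site (intcal.org) and place them
in this directory before installing, or point
`options(adnaprofile.curve_dir = "<dir>")` at a directory containing them.
`read_cal_curve()` parses the standard layout: `#` comment headers followed
by comma- or whitespace-separated columns `cal BP, 14C age BP, 1 sigma`.
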