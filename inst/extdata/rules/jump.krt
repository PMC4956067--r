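RULE JUMP
DISP head Y ABS>= 0.05 WITHIN 1 AS "Vertical movement of the head changes at least 5cm in under 1 second"
AND
DISP ankle_left Y ABS>= 0.05 WITHIN 1 AS "Vertical movement of the left ankle changes at least 5 cm in under 1 second"
AND
DISP ankle_right Y ABS>= 0.05 WITHIN 1 AS "Vertical movement of the right ankle changes at least 5 cm in under 1 second"
AND
DISP hip_centre Y ABS>= 0.05 WITHIN 1 AS "Vertical movement of the hip centre changes at least 5cm in under 1 second"
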