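>g1 synthetic protein
GQAEKLVLEIPPSGSALRYATLRSGIPSEFSSLLMVKGHVPPKTPLHGVFKISLDIRDFETQGDTKGYAMNHACRYGGYTPVEEN
>g2 synthetic protein
EDEAQSLAGDRVRSFAEALKAAPSIPISLEILSSDLLFLAIKETVIDYLGDDLALCKPPWVNLAIMAAE
>g3 synthetic protein
LSIALHHNGRFMWKLVMDVVQALSSAAYVVAKDGFDVHSPAHQRTALLMKAAAELDAPEFTAGGSGSIFTCLAFHKCNRKN
>g4 synthetic protein
VLLTEVTSATYQDIRWVTGSRDPIIAGTRYGGFLPKDNKALFPGFDFNDRILSIIDEQATVTQFPGPVQISDRYSGMGT
>g5 synthetic protein
NDEPSTTQVQGKSREKGLNLVVKVKCLLDFMLIPGVYARGQMRYTKYIPIYLGGTYEKCTDGGKMPELLDANK
>g6 synthetic protein
LESDASLLSEPHIEDVGIVMSGLNSVVEEEPNETEQIQSCVKVLGVDGKELFKVT
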