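condition	grasp	grasp_type	thumb_position	object_shape
1	large_diameter	power	abducted	large_bar
2	small_diameter	power	abducted	small_bar
3	medium_wrap	power	abducted	large_bar
4	adducted_thumb	power	adducted	small_bar
5	light_tool	power	adducted	small_bar
6	prismatic_4_finger	precision	abducted	small_bar
7	prismatic_3_finger	precision	abducted	small_bar
8	prismatic_2_finger	precision	abducted	small_bar
9	palmar_pinch	precision	abducted	card
10	power_disk	power	abducted	disk
11	power_sphere	power	abducted	large_sphere
12	precision_disk	precision	abducted	disk
13	precision_sphere	precision	abducted	large_sphere
14	tripod	precision	abducted	small_sphere
15	fixed_hook	power	adducted	large_bar
16	lateral	intermediate	adducted	card
17	index_finger_extension	power	adducted	small_bar
18	extension_type	power	abducted	card
19	distal_type	power	abducted	scissors
20	writing_tripod	intermediate	abducted	small_bar
21	tripod_variation	precision	abducted	small_sphere
22	parallel_extension	precision	abducted	card
23	adduction_grip	intermediate	adducted	small_bar
24	tip_pinch	precision	abducted	small_sphere
25	lateral_tripod	intermediate	abducted	small_bar
26	sphere_4_finger	precision	abducted	large_sphere
27	quadpod	precision	abducted	small_sphere
28	sphere_3_finger	precision	abducted	small_sphere
29	stick	intermediate	adducted	small_bar
30	palmar	power	adducted	card
31	ring	power	abducted	small_sphere
32	ventral	intermediate	adducted	small_bar
33	inferior_pincer	precision	abducted	small_sphere
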