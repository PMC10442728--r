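first_prompt_time: '13:30'
reminder_interval: 180.0
snooze_limit_time: '03:00'
response_window_end: '06:00'
expiry_notice_time: '10:00'
audio_target: 60.0
n_days: 15
closure_words:
- ok
- okay
- see you
- bye
- thank you
- thanks
- thx
emoji_closure: yes
max_followups: 2
typing_base: 0.5
typing_rate: 0.05
typing_max: 6.0
correction_keywords:
- correct
- fix
smfq_items:
- I feel sad today.
- I didn't enjoy anything today.
- I felt so tired that I just sat around today.
- I was very restless today.
- I felt I was no good today.
- I cried a lot today.
- I found it hard to think or concentrate today.
- I hated myself today.
- I felt I was a bad person today.
- I felt lonely today.
- I thought nobody really loved me today.
- I thought I could never be as good as others today.
- I felt I did everything wrong today.
smfq_anchors:
  '0': 'no'
  '1': sometimes
  '2': 'yes'
day_scripts:
  days:
    '1':
      q1: Can you introduce yourself?
      q2: What have you done today? Is your day going according to your usual routine?
    '3':
      q1: Are you at home?
      q1_yes: What are you doing? Is someone else around?
      q1_no: Who do you live with? Do you get along with the people you live with?
      q2: Can you tell me more about your house? Do you like living there?
    '5':
      q1: Did you go outside today at all, {name}? Do you spend more time inside,
        or do you sometimes go out? When you're out, what do you normally do?
      q2: And how's your neighborhood? Are there nice things around?
    '7':
      q1: Today I want to know about your favorite story. What is it? You can choose
        a movie, a series, a book... whatever you want!
      q2: And why is this your favorite story, {name}?
    '9':
      q1: Do you use your mobile phone a lot, {name}? What are your favorite things
        to do on the mobile phone?
      q2: And how much time do you think you spend on the internet each day? Do you
        use the internet mostly during the day or at night? Why?
    '11':
      q1: Not counting the audio recordings you send here :grinning_face_with_sweat:,
        who do you talk to about things that happen in your life? How's your relationship
        with this person?
      q2: And why do you trust this person?
    '13':
      q1: It's been almost 2 weeks since we started talking, {name}! How did you feel
        about answering these questions?
      q2: And how have you been in these last 2 weeks? Has anything different happened?
  followup1: Thank you for sending this audio! Tell us a little bit more about it,
    {name}!
  followup2: 'It would be very important if you could tell us a little more, okay?
    You can choose whether to send another audio recording: type ''yes'' or ''no''
    before sending it.'
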